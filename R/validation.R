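#' Compare a segmentation against simulator ground truth
#'
#' For every interior nucleus, looks up the segmented cell under the planted
#' nucleus centre and asks whether its set of cell-mates (other interior
#' nuclei sharing the same segmented cell) equals the ground-truth set of
#' cell-mates implied by the planted furrow failures. A nucleus therefore
#' only counts as matched when its whole cell was reconstructed correctly —
#' neither split nor merged.
#'
#' @param seg a [segment_embryo()] result.
#' @param lattice the [make_lattice()] used to simulate the image.
#' @param truth the matching [plant_failures()] ground truth.
#' @return List: `accuracy` (fraction of interior nuclei matched), `matched`
#'   (logical per interior nucleus), `n_interior`, `cell_of_nucleus_seg`.
#' @export
assignment_accuracy <- function(seg, lattice, truth) {
  interior <- truth$interior_tiles
  ctr <- cbind(round(truth$nucleus_centers[, 1]),
               round(truth$nucleus_centers[, 2]))
  seg_cell <- seg$cells[ctr]
  gt_cell <- truth$cell_of_nucleus
  matched <- vapply(seq_along(interior), function(k) {
    i <- interior[k]
    if (seg_cell[i] == 0L) return(FALSE)
    gt_mates <- interior[gt_cell[interior] == gt_cell[i]]
    seg_mates <- interior[seg_cell[interior] == seg_cell[i]]
    setequal(gt_mates, seg_mates)
  }, TRUE)
  list(accuracy = mean(matched), matched = matched,
       n_interior = length(interior), cell_of_nucleus_seg = seg_cell)
}
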