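# four-shade generation cycles per type: purples for A, greens for B
.PAL_A <- c("#3f007d", "#6a51a3", "#9e9ac8", "#dadaeb")
.PAL_B <- c("#00441b", "#238b45", "#74c476", "#c7e9c0")

#' Render a lattice snapshot
#'
#' Deterministic colouring: hue by label (purple for A, green for B),
#' with each lineage cycling through four shades by generation so division
#' events are visible; medium is white.  Identical states produce
#' byte-identical images.
#'
#' @param state A [cpm_state()].
#' @param path Optional PNG destination; when `NULL` only the raster is
#'   returned.
#' @return The H x W x 3 raster array (values in `[0, 1]`), invisibly when
#'   `path` is given.
#' @export
render_snapshot <- function(state, path = NULL) {
  g <- state$grid
  cells <- state$cells
  ncol_max <- max(c(cells$id, 1L))
  cols <- rep("#FFFFFF", ncol_max + 1L)  # index 1 = medium
  if (nrow(cells)) {
    shade <- cells$generation %% 4L + 1L
    cols[cells$id + 1L] <- ifelse(cells$label == "A",
                                  .PAL_A[shade], .PAL_B[shade])
  }
  rgb <- grDevices::col2rgb(cols) / 255
  idx <- t(g) + 1L  # rows = y for the image
  img <- array(0, dim = c(nrow(idx), ncol(idx), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(rgb[ch, idx], nrow(idx), ncol(idx))
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}
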