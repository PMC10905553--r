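# Binary 3D morphology on logical arrays. Labelling is done in C++
# (src/morphology.cpp); erosion/dilation use vectorised array shifts with a
# radius-1 cross (6-neighbourhood) structuring element, applied `radius`
# times. Out-of-grid neighbours count as background.

label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  lab <- label_components_cpp(as.logical(mask), as.integer(dim(mask)),
                              as.integer(connectivity))
  array(lab, dim(mask))
}

component_sizes <- function(labels) {
  labels <- labels[labels > 0L]
  if (length(labels) == 0L) return(integer(0))
  tabulate(labels)
}

largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  sizes <- component_sizes(lab)
  if (length(sizes) == 0L) return(NULL)
  lab == which.max(sizes)
}

shift_array <- function(x, d, fill = FALSE) {
  # shift logical array by integer offset d (length 3), filling with `fill`
  dm <- dim(x)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (d[a] >= 0) {
      src[[a]] <- seq_len(dm[a] - d[a])
      dst[[a]] <- src[[a]] + d[a]
    } else {
      src[[a]] <- seq.int(1 - d[a], dm[a])
      dst[[a]] <- src[[a]] + d[a]
    }
    if (abs(d[a]) >= dm[a]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

cross_neighbours <- rbind(
  c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

binary_dilate <- function(mask, radius = 1L) {
  out <- mask
  for (r in seq_len(radius)) {
    acc <- out
    for (q in seq_len(nrow(cross_neighbours)))
      acc <- acc | shift_array(out, cross_neighbours[q, ], fill = FALSE)
    out <- acc
  }
  out
}

binary_erode <- function(mask, radius = 1L) {
  out <- mask
  for (r in seq_len(radius)) {
    acc <- out
    for (q in seq_len(nrow(cross_neighbours)))
      acc <- acc & shift_array(out, cross_neighbours[q, ], fill = FALSE)
    out <- acc
  }
  out
}

binary_opening <- function(mask, radius = 1L) {
  binary_dilate(binary_erode(mask, radius), radius)
}

#' Fill internal holes of a binary mask
#'
#' Background components (6-connected) not touching the array border are
#' considered internal cavities and are added to the mask; used so that the
#' air-filled lungs end up inside the body mask.
#' @param mask logical 3D array.
#' @return logical 3D array with cavities filled.
#' @keywords internal
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, connectivity = 6L)
  d <- dim(mask)
  border <- unique(c(
    lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
    lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0L]
  outside <- array(lab %in% border, d)
  mask | (bg & !outside)
}
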