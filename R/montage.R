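#' Standard 64-channel montage
#'
#' Head-plane electrode coordinates on the unit disk (x = right, y = anterior)
#' for a 64-channel extended 10-20 layout including linked mastoids M1/M2.
#' Used to construct canonical template maps and for topographic plotting.
#'
#' @param channels optional subset/order of labels to return.
#' @return A tibble with columns `channel`, `x`, `y`.
#' @export
#' @examples
#' default_montage()
default_montage <- function(channels = NULL) {
  rows <- list(
    list(y = 0.90, labs = c("FP1", "FPZ", "FP2"), xs = c(-0.25, 0, 0.25)),
    list(y = 0.75, labs = c("AF7", "AF3", "AF4", "AF8"),
         xs = c(-0.55, -0.30, 0.30, 0.55)),
    list(y = 0.60, labs = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8"),
         xs = c(-0.75, -0.55, -0.40, -0.20, 0, 0.20, 0.40, 0.55, 0.75)),
    list(y = 0.30, labs = c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4",
                            "FC6", "FT8"),
         xs = c(-0.85, -0.62, -0.42, -0.21, 0, 0.21, 0.42, 0.62, 0.85)),
    list(y = 0.00, labs = c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8"),
         xs = c(-0.95, -0.70, -0.46, -0.23, 0, 0.23, 0.46, 0.70, 0.95)),
    list(y = -0.30, labs = c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4",
                             "CP6", "TP8"),
         xs = c(-0.85, -0.62, -0.42, -0.21, 0, 0.21, 0.42, 0.62, 0.85)),
    list(y = -0.60, labs = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8"),
         xs = c(-0.75, -0.55, -0.40, -0.20, 0, 0.20, 0.40, 0.55, 0.75)),
    list(y = -0.80, labs = c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8"),
         xs = c(-0.55, -0.40, -0.22, 0, 0.22, 0.40, 0.55)),
    list(y = -0.95, labs = c("O1", "OZ", "O2"), xs = c(-0.25, 0, 0.25)),
    list(y = -0.40, labs = c("M1", "M2"), xs = c(-1.0, 1.0)))
  mont <- tibble::tibble(
    channel = unlist(lapply(rows, `[[`, "labs")),
    x = unlist(lapply(rows, `[[`, "xs")),
    y = unlist(lapply(rows, function(r) rep(r$y, length(r$labs)))))
  if (!is.null(channels)) {
    miss <- setdiff(channels, mont$channel)
    if (length(miss)) stop("channels not in montage: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    mont <- mont[match(channels, mont$channel), ]
  }
  mont
}

montage_coords <- function(montage, channels) {
  miss <- setdiff(channels, montage$channel)
  if (length(miss)) stop("montage lacks channel(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m <- montage[match(channels, montage$channel), ]
  if (!all(is.finite(m$x)) || !all(is.finite(m$y))) {
    stop("montage coordinates must be finite", call. = FALSE)
  }
  m
}
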