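#' Standard 60-channel EEG montage
#'
#' The 60 scalp electrodes of the extended international 10-20 layout used
#' throughout this package, in canonical order. All preprocessing and
#' connectivity stages operate on (subsets of) this montage.
#'
#' @return Character vector of 60 electrode names.
#' @export
#' @examples
#' length(standard_montage())
standard_montage <- function() {
  c("FP1", "FPZ", "FP2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
    "O1", "OZ", "O2")
}

#' Key sensorimotor electrodes per hemisphere
#'
#' Fifteen frontal-central-parietal electrodes on each hemisphere over which
#' nodal network metrics are averaged before computing left-right differences.
#'
#' @param side `"left"` or `"right"`.
#' @return Character vector of 15 electrode names.
#' @export
hemisphere_electrodes <- function(side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") {
    c("F5", "F3", "F1", "FC5", "FC3", "FC1", "C5", "C3", "C1",
      "CP5", "CP3", "CP1", "P5", "P3", "P1")
  } else {
    c("F6", "F4", "F2", "FC6", "FC4", "FC2", "C6", "C4", "C2",
      "CP6", "CP4", "CP2", "P6", "P4", "P2")
  }
}

#' Default 21-channel sensorimotor subset
#'
#' Three transverse rows of seven electrodes (frontal-central, central,
#' centro-parietal) covering the sensorimotor strip; the default channel
#' subset for the PSD, wavelet and Riemannian feature extractors.
#'
#' @return Character vector of 21 electrode names.
#' @export
sensorimotor_channels <- function() {
  c("FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6",
    "C5",  "C3",  "C1",  "CZ",  "C2",  "C4",  "C6",
    "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6")
}

# Approximate 2-D projected coordinates for the 60-channel montage.
# Rows of the 10-20 grid are mapped to horizontal lines (front positive y),
# odd numbers to the left (negative x). Sufficient for distance-based
# neighbour interpolation; not a spherical head model.
montage_coordinates <- function(channels = standard_montage()) {
  row_y <- c(FP = 0.90, AF = 0.70, F = 0.50, FT = 0.28, FC = 0.25,
             T = 0.00, C = 0.00, TP = -0.28, CP = -0.25,
             P = -0.50, PO = -0.70, O = -0.90)
  parse_one <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Z]+)([0-9]+|Z)$", lab))[[1]]
    prefix <- m[2]; idx <- m[3]
    y <- row_y[[prefix]]
    if (idx == "Z") {
      x <- 0
    } else {
      k <- as.integer(idx)
      # odd indices left, even right; larger index = more lateral
      x <- ceiling(k / 2) * 0.16 * if (k %% 2 == 1) -1 else 1
      if (prefix %in% c("T", "FT", "TP")) x <- sign(x) * 1.0
      if (prefix %in% c("FP", "O")) x <- sign(x) * 0.30
    }
    c(x = x, y = y)
  }
  xy <- t(vapply(channels, parse_one, c(x = 0, y = 0)))
  rownames(xy) <- channels
  xy
}

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's random state afterwards. All seeded operations in the package
# funnel through here so determinism contracts hold without clobbering the
# session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-subject substream seed from a master seed by a fixed counter
# scheme (documented: master * 10007 + index, folded into 32-bit range).
substream_seed <- function(master, index) {
  as.integer((as.numeric(master) * 10007 + index) %% 2147483647)
}
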