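# Electrode montage: 32-channel 10/20 cap with mirror pairs and the
# posterior/midline subsets used by the P1 biomarkers.

#' Standard 32-electrode 10/20 montage
#'
#' Builds the recording montage used throughout the package: 32 electrodes of
#' the extended 10/20 system with schematic unit-sphere positions, left/right
#' mirror pairs across the nasion-inion axis, the 13-electrode posterior
#' subset over which the mean posterior P1 (MPP1) biomarker is computed, and
#' the midline subset.
#'
#' Positions are schematic 10/20 coordinates on the unit sphere (head frame:
#' x right, y anterior, z up). Named anchor electrodes sit at their textbook
#' inclination/azimuth; intermediate electrodes are spherical midpoints of
#' neighbouring anchors. The positions are used for electrode adjacency in
#' cluster-based permutation tests and for topographic weighting in the
#' simulator; they are not digitised head coordinates.
#'
#' @return An object of class `verp_montage`: a list with elements
#'   \describe{
#'     \item{labels}{character vector of the 32 electrode names.}
#'     \item{pos}{32 x 3 numeric matrix of unit-sphere coordinates
#'       (rows named by electrode).}
#'     \item{mirror}{named character vector mapping each electrode to its
#'       mirror partner across the nasion-inion axis (midline electrodes map
#'       to themselves).}
#'     \item{posterior}{character vector, the 13 posterior electrodes.}
#'     \item{midline}{character vector, the midline electrodes.}
#'   }
#' @examples
#' m <- standard_montage()
#' m$mirror[["P7"]]   # "P8"
#' length(m$posterior) # 13
#' @export
standard_montage <- function() {
  sph <- function(incl, az) {
    incl <- incl * pi / 180; az <- az * pi / 180
    c(sin(incl) * sin(az), sin(incl) * cos(az), cos(incl))
  }
  # spherical midpoint (both inputs unit vectors)
  smid <- function(a, b) { v <- a + b; v / sqrt(sum(v^2)) }

  pos <- list(
    Cz  = sph(0, 0),
    Fz  = sph(45, 0),  FCz = sph(22.5, 0), Pz = sph(45, 180),
    FP1 = sph(90, -18),  FP2 = sph(90, 18),
    F7  = sph(90, -54),  F8  = sph(90, 54),
    T7  = sph(90, -90),  T8  = sph(90, 90),
    P7  = sph(90, -126), P8  = sph(90, 126),
    O1  = sph(90, -162), O2  = sph(90, 162),
    TP9 = sph(110, -100), TP10 = sph(110, 100),
    F9  = sph(110, -54),  F10  = sph(110, 54)
  )
  pos$F3  <- smid(pos$Fz, pos$F7);  pos$F4  <- smid(pos$Fz, pos$F8)
  pos$C3  <- smid(pos$Cz, pos$T7);  pos$C4  <- smid(pos$Cz, pos$T8)
  pos$P3  <- smid(pos$Pz, pos$P7);  pos$P4  <- smid(pos$Pz, pos$P8)
  pos$FC1 <- smid(pos$Fz, pos$C3);  pos$FC2 <- smid(pos$Fz, pos$C4)
  pos$FC5 <- smid(pos$F7, pos$C3);  pos$FC6 <- smid(pos$F8, pos$C4)
  pos$CP1 <- smid(pos$Pz, pos$C3);  pos$CP2 <- smid(pos$Pz, pos$C4)
  pos$CP5 <- smid(pos$P7, pos$C3);  pos$CP6 <- smid(pos$P8, pos$C4)

  labels <- c("FP1", "FP2", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FCz", "FC2", "FC6",
              "T7", "C3", "Cz", "C4", "T8",
              "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
              "P7", "P3", "Pz", "P4", "P8", "O1", "O2", "F9", "F10")
  pm <- t(vapply(labels, function(l) pos[[l]], numeric(3)))
  colnames(pm) <- c("x", "y", "z")

  pairs <- c(FP1 = "FP2", F7 = "F8", F3 = "F4", FC5 = "FC6", FC1 = "FC2",
             T7 = "T8", C3 = "C4", TP9 = "TP10", CP5 = "CP6", CP1 = "CP2",
             P7 = "P8", P3 = "P4", O1 = "O2", F9 = "F10")
  mirror <- stats::setNames(labels, labels)
  mirror[names(pairs)] <- pairs
  mirror[unname(pairs)] <- names(pairs)

  structure(list(
    labels = labels,
    pos = pm,
    mirror = mirror,
    posterior = c("TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
                  "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
    midline = c("Fz", "FCz", "Cz", "Pz")
  ), class = "verp_montage")
}

#' Electrode adjacency from scalp distance
#'
#' Two electrodes are neighbours when the straight-line (chord) distance
#' between their unit-sphere positions is below `radius`. Used to define
#' spatial contiguity for cluster-based permutation tests.
#'
#' @param montage a `verp_montage`.
#' @param electrodes electrodes to include (default all).
#' @param radius neighbourhood radius in unit-sphere chord units
#'   (default 0.65, approximately 38 degrees of arc: the smallest radius
#'   that connects neighbouring 10/20 electrodes).
#' @return Symmetric logical matrix (diagonal `FALSE`) named by electrode.
#' @export
electrode_adjacency <- function(montage, electrodes = montage$labels,
                                radius = 0.65) {
  stopifnot(inherits(montage, "verp_montage"))
  miss <- setdiff(electrodes, montage$labels)
  if (length(miss)) stop("unknown electrodes: ", paste(miss, collapse = ", "))
  p <- montage$pos[electrodes, , drop = FALSE]
  d <- as.matrix(stats::dist(p))
  adj <- d < radius
  diag(adj) <- FALSE
  dimnames(adj) <- list(electrodes, electrodes)
  adj
}

#' @export
print.verp_montage <- function(x, ...) {
  cat("<verp_montage> 32-electrode 10/20 cap\n")
  cat("  posterior subset:", paste(x$posterior, collapse = " "), "\n")
  cat("  midline subset:  ", paste(x$midline, collapse = " "), "\n")
  invisible(x)
}
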