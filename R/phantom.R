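# Digital phantom for readout-comparison simulations.

# Ground-truth relaxation times of the five phantom regions (ms).
PHANTOM_T2STAR <- c(49, 78, 69, 99, 133)
PHANTOM_T1 <- c(671, 959, 878, 1134, 1372)

#' Build the five-region digital phantom
#'
#' A disc-shaped object containing five circular regions with ground-truth
#' (T2*, T1) pairs of (49, 671), (78, 959), (69, 878), (99, 1134) and
#' (133, 1372) ms. Region 3 (T2* = 69 ms) sits at the centre; the other
#' four are placed on the diagonals. Label 0 is noise-only background, and
#' four corner rectangles are guaranteed to lie outside the disc so that
#' background-noise statistics can always be measured there (>= 300 voxels
#' per corner at the default 240 x 240 matrix).
#'
#' Geometry scales with the matrix size: region radius 0.11, disc radius
#' 0.46 and corner-box side 0.10 of the smaller matrix dimension.
#'
#' @param matrix Image dimensions `c(rows, columns)`, each >= 64.
#' @return An object of class `digital_phantom` with fields `label_map`
#'   (integer matrix, 0 = background), `regions` (data.frame of per-region
#'   tissue parameters), `matrix`, and `corner_size`.
#' @export
build_default_phantom <- function(matrix = c(240, 240)) {
  if (length(matrix) == 1) matrix <- c(matrix, matrix)
  nr <- as.integer(matrix[1]); nc <- as.integer(matrix[2])
  if (nr < 64 || nc < 64)
    stop("matrix must be at least 64 x 64 to host five regions and corner ROIs")
  m <- min(nr, nc)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  disc_r <- 0.46 * m
  reg_r <- 0.11 * m
  offs <- 0.27 * m
  ang <- c(45, 135, 315, 225) * pi / 180  # regions 1, 2, 4, 5
  centers <- rbind(
    ctr + offs * c(cos(ang[1]), sin(ang[1])),
    ctr + offs * c(cos(ang[2]), sin(ang[2])),
    ctr,
    ctr + offs * c(cos(ang[3]), sin(ang[3])),
    ctr + offs * c(cos(ang[4]), sin(ang[4])))
  row_i <- base::matrix(seq_len(nr), nr, nc)
  col_i <- base::matrix(seq_len(nc), nr, nc, byrow = TRUE)
  label <- base::matrix(0L, nr, nc)
  for (k in 1:5) {
    d2 <- (row_i - centers[k, 1])^2 + (col_i - centers[k, 2])^2
    inside <- d2 <= reg_r^2
    if (any(label[inside] != 0L)) stop("internal error: phantom regions overlap")
    label[inside] <- k
  }
  # sanity: regions inside disc, corner boxes outside it
  d2c <- (row_i - ctr[1])^2 + (col_i - ctr[2])^2
  if (any(label != 0L & d2c > disc_r^2))
    stop("internal error: a phantom region extends beyond the disc")
  cs <- max(8L, as.integer(round(0.10 * m)))
  corner_d2 <- (min(cs, nr) - ctr[1])^2 + (min(cs, nc) - ctr[2])^2
  if (corner_d2 <= disc_r^2)
    stop("matrix too small: corner background ROIs would intersect the phantom disc")
  regions <- data.frame(roi = 1:5, m0 = 1,
                        t1 = PHANTOM_T1, t2_star = PHANTOM_T2STAR,
                        phi0 = 0, delta_f = 0)
  structure(list(label_map = label, regions = regions,
                 matrix = c(nr, nc), corner_size = cs),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("<digital_phantom> %d x %d, 5 regions (T2* %s ms)\n",
              x$matrix[1], x$matrix[2],
              paste(x$regions$t2_star, collapse = "/")))
  invisible(x)
}

#' Logical mask of one phantom region
#' @param phantom A [build_default_phantom()] object.
#' @param roi Region id (1-5).
#' @return Logical matrix.
#' @export
region_mask <- function(phantom, roi) {
  stopifnot(inherits(phantom, "digital_phantom"))
  phantom$label_map == as.integer(roi)
}

#' Corner background masks of the phantom
#'
#' The four noise-only rectangles at the image corners, used for Rayleigh
#' background noise estimation.
#'
#' @param phantom A [build_default_phantom()] object.
#' @return A list of four logical matrices.
#' @export
corner_masks <- function(phantom) {
  stopifnot(inherits(phantom, "digital_phantom"))
  nr <- phantom$matrix[1]; nc <- phantom$matrix[2]
  cs <- phantom$corner_size
  mk <- function(rows, cols) {
    m <- matrix(FALSE, nr, nc)
    m[rows, cols] <- TRUE
    m
  }
  list(mk(1:cs, 1:cs),
       mk(1:cs, (nc - cs + 1):nc),
       mk((nr - cs + 1):nr, 1:cs),
       mk((nr - cs + 1):nr, (nc - cs + 1):nc))
}

#' Tissue parameters of one phantom region
#' @param phantom A [build_default_phantom()] object.
#' @param roi Region id (1-5).
#' @return A [tissue_params()].
#' @export
region_tissue <- function(phantom, roi) {
  stopifnot(inherits(phantom, "digital_phantom"))
  r <- phantom$regions[phantom$regions$roi == roi, ]
  if (nrow(r) != 1) stop("unknown region: ", roi)
  tissue_params(m0 = r$m0, t1 = r$t1, t2_star = r$t2_star,
                phi0 = r$phi0, delta_f = r$delta_f)
}
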