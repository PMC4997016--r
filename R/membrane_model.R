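#' Binary domain masks
#'
#' A `domain_mask` marks the liquid-ordered (Lo) regions of a rectangular
#' patch of membrane as `TRUE` on a pixel grid. Rows index y, columns index x;
#' the point at the centre of pixel (1,1) sits at `origin_um`. Points outside
#' the mask extent are treated as liquid-disordered (Ld).
#'
#' @param mask Logical matrix (`TRUE` = Lo).
#' @param pixel_size_nm Pixel edge in nm.
#' @param origin_um Length-2 numeric, position (x, y) in um of the centre of
#'   pixel `[1, 1]`.
#' @return An object of class `domain_mask`.
#' @export
domain_mask <- function(mask, pixel_size_nm, origin_um = c(0, 0)) {
  stopifnot(is.matrix(mask))
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  stop_if_not_scalar_num(pixel_size_nm, "pixel_size_nm", 0, strict = TRUE)
  stopifnot(length(origin_um) == 2, all(is.finite(origin_um)))
  if (length(mask) == 0L) stop("mask must be non-empty")
  structure(list(mask = mask, pixel_size_nm = pixel_size_nm,
                 origin_um = as.numeric(origin_um)),
            class = "domain_mask")
}

#' @rdname domain_mask
#' @param radius_um Disk radius in um.
#' @param extent_um Length of the square field in um.
#' @param pixel_size_nm Pixel edge in nm.
#' @description `disk_domain_mask()` builds the canonical test geometry: one
#' circular Lo domain centred in a square Ld field.
#' @export
disk_domain_mask <- function(radius_um, extent_um = 4 * radius_um,
                             pixel_size_nm = 20) {
  px <- pixel_size_nm * 1e-3
  n <- max(3L, ceiling(extent_um / px))
  cx <- ((seq_len(n)) - 1) * px - (n - 1) * px / 2
  m <- outer(cx, cx, function(y, x) x^2 + y^2 <= radius_um^2)
  domain_mask(m, pixel_size_nm, origin_um = c(cx[1], cx[1]))
}

# TRUE where (x, y) falls on an Lo pixel (nearest-pixel lookup); FALSE outside
# the mask extent.
mask_lookup <- function(dm, x_um, y_um) {
  px <- dm$pixel_size_nm * 1e-3
  j <- round((x_um - dm$origin_um[1]) / px) + 1
  i <- round((y_um - dm$origin_um[2]) / px) + 1
  ok <- i >= 1 & i <= nrow(dm$mask) & j >= 1 & j <= ncol(dm$mask)
  out <- logical(length(x_um))
  out[ok] <- dm$mask[cbind(i[ok], j[ok])]
  out
}

# Area of the Lo phase in um^2 (pixel counting).
mask_lo_area_um2 <- function(dm) {
  sum(dm$mask) * (dm$pixel_size_nm * 1e-3)^2
}

#' Membrane model with nanoscopic traps
#'
#' Describes the raft-mimetic geometry driving [simulate_membrane()]: an Lo
#' domain mask plus a field of circular nano-traps (the putative clusters of
#' densely packed saturated lipids) inside the Lo phase. Traps confine the
#' particle by a reflecting boundary; escape is a Poisson event. Trap
#' diameters are drawn from a truncated normal distribution (default
#' 32 +/- 10 nm, the detected confinement-size statistics) and trap placement
#' is random sequential adsorption (non-overlapping) until the requested area
#' fraction of the Lo phase is covered.
#'
#' @param lo_mask A [domain_mask()].
#' @param trap_area_fraction Fraction of the Lo area covered by traps, in
#'   `[0, 1)`. The realized fraction is reported in the returned object and is
#'   required to be within 10% (relative) of the request.
#' @param trap_diameter_mean_nm,trap_diameter_sd_nm Trap diameter distribution
#'   (truncated at > 4 nm), defaults 32 and 10 nm.
#' @param trap_escape_rate_s Poisson escape rate in 1/s; default `1/0.62e-3`
#'   (mean residence 0.62 ms).
#' @param seed Optional seed for the trap draw.
#' @return An object of class `membrane_model` with elements `lo_mask`,
#'   `trap_x`, `trap_y`, `trap_r_um`, `trap_escape_rate_s`,
#'   `trap_area_fraction` (requested) and `realized_area_fraction`.
#' @examples
#' mm <- membrane_model(disk_domain_mask(0.5), trap_area_fraction = 0.2, seed = 1)
#' @export
membrane_model <- function(lo_mask,
                           trap_area_fraction = 0.30,
                           trap_diameter_mean_nm = 32,
                           trap_diameter_sd_nm = 10,
                           trap_escape_rate_s = 1 / 0.62e-3,
                           seed = NULL) {
  stopifnot(inherits(lo_mask, "domain_mask"))
  stop_if_not_scalar_num(trap_area_fraction, "trap_area_fraction", 0)
  if (trap_area_fraction >= 1) stop("trap_area_fraction must be < 1")
  stop_if_not_scalar_num(trap_escape_rate_s, "trap_escape_rate_s", 0, strict = TRUE)

  traps <- with_seed(seed, place_traps(lo_mask, trap_area_fraction,
                                       trap_diameter_mean_nm, trap_diameter_sd_nm))
  lo_area <- mask_lo_area_um2(lo_mask)
  realized <- sum(pi * traps$r^2) / lo_area
  if (trap_area_fraction > 0 &&
      abs(realized - trap_area_fraction) > 0.1 * trap_area_fraction) {
    stop(sprintf(paste0("could not realize trap area fraction %.3g ",
                        "(achieved %.3g); the Lo geometry may be too small or the ",
                        "fraction too close to the disk-packing limit"),
                 trap_area_fraction, realized))
  }
  structure(list(lo_mask = lo_mask,
                 trap_x = traps$x, trap_y = traps$y, trap_r_um = traps$r,
                 trap_escape_rate_s = trap_escape_rate_s,
                 trap_area_fraction = trap_area_fraction,
                 realized_area_fraction = realized,
                 trap_diameter_mean_nm = trap_diameter_mean_nm,
                 trap_diameter_sd_nm = trap_diameter_sd_nm),
            class = "membrane_model")
}

# Random sequential adsorption of non-overlapping disks on the Lo pixels of
# the mask, stopping when the target area fraction is reached. Uses a coarse
# bucket grid for neighbour queries so dense fields stay fast.
place_traps <- function(dm, target_fraction, mean_nm, sd_nm) {
  if (target_fraction <= 0) {
    return(list(x = numeric(0), y = numeric(0), r = numeric(0)))
  }
  lo_area <- mask_lo_area_um2(dm)
  if (lo_area <= 0) stop("lo_mask has no Lo pixels but trap_area_fraction > 0")
  target_area <- target_fraction * lo_area

  px <- dm$pixel_size_nm * 1e-3
  lo_idx <- which(dm$mask, arr.ind = TRUE)
  lo_x <- dm$origin_um[1] + (lo_idx[, 2] - 1) * px
  lo_y <- dm$origin_um[2] + (lo_idx[, 1] - 1) * px

  cell <- max(2 * (mean_nm + 4 * sd_nm) * 1e-3, 4 * px)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  bkey <- function(bx, by) paste0(bx, ",", by)

  xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
  area <- 0
  max_attempts <- 400 * ceiling(target_area / (pi * (mean_nm * 1e-3 / 2)^2)) + 2000
  attempts <- 0
  while (area < target_area && attempts < max_attempts) {
    attempts <- attempts + 1
    k <- sample.int(length(lo_x), 1L)
    # jitter within the pixel so centres are continuous
    x <- lo_x[k] + runif(1, -px / 2, px / 2)
    y <- lo_y[k] + runif(1, -px / 2, px / 2)
    d_nm <- rnorm(1, mean_nm, sd_nm)
    if (d_nm <= 4) next
    r <- d_nm * 1e-3 / 2
    bx <- floor(x / cell); by <- floor(y / cell)
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      nb <- buckets[[bkey(bx + dx, by + dy)]]
      if (!is.null(nb)) {
        dd <- (xs[nb] - x)^2 + (ys[nb] - y)^2
        if (any(dd < (rs[nb] + r)^2)) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
    key <- bkey(bx, by)
    buckets[[key]] <- c(buckets[[key]], length(xs))
    area <- area + pi * r^2
  }
  list(x = xs, y = ys, r = rs)
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf(paste0("Membrane model: %d traps, diameters %.3g +/- %.3g nm, ",
                     "escape rate %.3g /s (mean residence %.3g ms)\n"),
              length(x$trap_x), x$trap_diameter_mean_nm, x$trap_diameter_sd_nm,
              x$trap_escape_rate_s, 1e3 / x$trap_escape_rate_s))
  cat(sprintf("  Lo area %.3g um^2, trap area fraction %.3g (requested %.3g)\n",
              mask_lo_area_um2(x$lo_mask), x$realized_area_fraction,
              x$trap_area_fraction))
  invisible(x)
}
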