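#' Synthetic test images
#'
#' Deterministic, seeded image fixtures with known structure, so solvers
#' and target constructors can be exercised without external data:
#'
#' * `"constant"` — every pixel equal to `amplitude`.
#' * `"ramp"` — horizontal linear ramp spanning `amplitude` around 0.5.
#' * `"step_edge"` — two-level image, `levels[1]` left of `edge_position`,
#'   `levels[2]` from it onwards; a single column of gradient, the
#'   canonical halo-measurement fixture.
#' * `"disk"` — bright disk (radius `min(H, W)/4`) on a dark background.
#' * `"red_green_chart"` — a checkerboard of reddish/greenish patches
#'   whose colours differ mainly along the `(1, -1, 0)` red-green axis
#'   (with a small blue modulation), i.e. along a protan/deutan confusion
#'   direction: its structure largely vanishes under deficiency
#'   simulation, which is what daltonisation must repair.
#' * `"smooth_random"` — seeded uniform noise smoothed by repeated
#'   separable binomial (`[1,2,1]/4`) passes, rescaled to \[0.1, 0.9\]: a
#'   smooth random field with interior extrema and no saturation.
#'
#' The same arguments and seed always produce the identical array; the
#' caller's RNG state is left untouched.
#'
#' @param kind Fixture kind (see above).
#' @param height,width Dimensions in pixels (at least 8 for solver use).
#' @param channels 1 or 3; defaults to 3 for `"red_green_chart"`, else 1.
#' @param seed Integer seed (only `"smooth_random"` draws random numbers).
#' @param amplitude Level/span parameter, default 0.5 (0.8 for `"ramp"`).
#' @param edge_position Column index of the step for `"step_edge"`
#'   (default `floor(width/2) + 1`).
#' @param levels Two-level vector for `"step_edge"`, default `c(0.2, 0.8)`.
#' @return An image field `H x W x C`.
#' @examples
#' u <- fixture_image("step_edge", 16, 16)
#' range(u)
#' @export
fixture_image <- function(kind = c("constant", "ramp", "step_edge", "disk",
                                   "red_green_chart", "smooth_random"),
                          height = 64L, width = 64L, channels = NULL,
                          seed = 1L, amplitude = NULL,
                          edge_position = NULL, levels = c(0.2, 0.8)) {
  kind <- match.arg(kind)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 2L || width < 2L) {
    stop("fixture dimensions must be at least 2 x 2", call. = FALSE)
  }
  if (is.null(channels)) {
    channels <- if (kind == "red_green_chart") 3L else 1L
  }
  channels <- as.integer(channels)
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3", call. = FALSE)
  if (kind == "red_green_chart" && channels != 3L) {
    stop("red_green_chart is a colour fixture (channels = 3)", call. = FALSE)
  }
  u <- switch(kind,
    constant = {
      a <- if (is.null(amplitude)) 0.5 else amplitude
      array(a, c(height, width, channels))
    },
    ramp = {
      a <- if (is.null(amplitude)) 0.8 else amplitude
      row_vals <- 0.5 + a * (seq_len(width) - (width + 1) / 2) / (width - 1)
      array(rep(rep(row_vals, each = height), channels),
            c(height, width, channels))
    },
    step_edge = {
      pos <- if (is.null(edge_position)) width %/% 2L + 1L else as.integer(edge_position)
      stopifnot(pos >= 2L, pos <= width)
      m <- matrix(levels[1], height, width)
      m[, pos:width] <- levels[2]
      array(rep(m, channels), c(height, width, channels))
    },
    disk = {
      a <- if (is.null(amplitude)) 0.5 else amplitude
      cy <- (height + 1) / 2; cx <- (width + 1) / 2
      r <- min(height, width) / 4
      d2 <- outer((seq_len(height) - cy)^2, (seq_len(width) - cx)^2, `+`)
      m <- matrix(0.25, height, width)
      m[d2 <= r^2] <- 0.25 + a
      array(rep(m, channels), c(height, width, channels))
    },
    red_green_chart = {
      ph <- max(2L, height %/% 4L)
      pw <- max(2L, width %/% 4L)
      pi_ <- (seq_len(height) - 1L) %/% ph
      pj <- (seq_len(width) - 1L) %/% pw
      parity <- outer(pi_, pj, `+`) %% 2L          # red vs green patches
      sep <- 0.4 + 0.1 * (outer(pi_, 2L * pj, `+`) %% 2L)  # separation 0.4/0.5
      half <- sep / 2
      u <- array(0, c(height, width, 3L))
      u[, , 1] <- 0.5 + ifelse(parity == 0L, half, -half)
      u[, , 2] <- 0.5 - ifelse(parity == 0L, half, -half)
      u[, , 3] <- 0.45 + 0.05 * (outer(pi_, 3L * pj, `+`) %% 2L)
      u
    },
    smooth_random = {
      old_seed <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      on.exit({
        if (is.null(old_seed)) {
          if (exists(".Random.seed", envir = globalenv())) {
            rm(".Random.seed", envir = globalenv())
          }
        } else assign(".Random.seed", old_seed, envir = globalenv())
      })
      set.seed(as.integer(seed))
      u <- array(runif(height * width * channels), c(height, width, channels))
      for (pass in 1:8) {
        u <- .smooth121(u, along = "rows")
        u <- .smooth121(u, along = "cols")
      }
      lo <- min(u); hi <- max(u)
      if (hi > lo) u <- 0.1 + 0.8 * (u - lo) / (hi - lo) else u[] <- 0.5
      u
    }
  )
  as_image_field(u)
}

# one [1,2,1]/4 binomial pass with replicate boundary, per channel
.smooth121 <- function(u, along = c("rows", "cols")) {
  along <- match.arg(along)
  d <- dim(u)
  H <- d[1]; W <- d[2]
  if (along == "rows") {
    up <- u[c(1L, seq_len(H - 1L)), , , drop = FALSE]
    dn <- u[c(seq_len(H - 1L) + 1L, H), , , drop = FALSE]
  } else {
    up <- u[, c(1L, seq_len(W - 1L)), , drop = FALSE]
    dn <- u[, c(seq_len(W - 1L) + 1L, W), , drop = FALSE]
  }
  (up + 2 * u + dn) / 4
}

#' Out-of-range overshoot (halo) metric
#'
#' Quantifies haloing as the largest overshoot of `result` beyond the
#' per-channel \[min, max\] range of `source`: 0 means no pixel exceeds
#' the source range in any channel. Unconstrained Poisson reintegration
#' of an amplified gradient field produces large overshoot near strong
#' edges; the anisotropic solvers are designed to suppress it.
#'
#' @param result Processed image field.
#' @param source Reference image field of the same shape.
#' @return A single non-negative number.
#' @export
halo_metric <- function(result, source) {
  r <- as_image_field(result, check = FALSE)
  s <- as_image_field(source, check = FALSE)
  if (!identical(dim(r), dim(s))) {
    stop("result and source must have identical dimensions", call. = FALSE)
  }
  C <- dim(r)[3]
  worst <- 0
  for (ch in seq_len(C)) {
    rc <- r[, , ch]; sc <- s[, , ch]
    worst <- max(worst, max(rc) - max(sc), min(sc) - min(rc))
  }
  max(0, worst)
}
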