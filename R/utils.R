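# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (strict_lower && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("'%s' must be >= %g", name, lower)
  if (x > upper) stopf("'%s' must be <= %g", name, upper)
  invisible(x)
}

# Sample-standard-deviation Wilson score interval, 95% by default.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

# Bilinear interpolation of a coarse matrix `m` (unit spacing, node (1,1) at
# coordinate (0,0)) at arbitrary (gx, gy) in node units.
bilinear_at <- function(m, gx, gy) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- pmin(pmax(gx, 0), nc - 1 - 1e-9)
  gy <- pmin(pmax(gy, 0), nr - 1 - 1e-9)
  j0 <- floor(gx); i0 <- floor(gy)
  fx <- gx - j0; fy <- gy - i0
  i0 <- i0 + 1; j0 <- j0 + 1
  m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    m[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    m[cbind(i0 + 1, j0)] * (1 - fx) * fy +
    m[cbind(i0 + 1, j0 + 1)] * fx * fy
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
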