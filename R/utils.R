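# Internal helpers shared across modules.

#' @importFrom stats mad median quantile rnorm runif rpois rlnorm qlnorm sd
#'   var approx cor lm coef pnorm pt uniroot setNames complete.cases dist
#'   hclust cutree
NULL

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the session stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed) %% 2147483647L)
  }
  force(code)
}

# Counter-based child-seed derivation: reproducible per (seed, k), no
# collisions across the small counter ranges used by the cohort generator.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483563 * 48271 + as.double(k) * 8191) %%
               2147483563) + 1L
}

# Robust background scale: MAD with a floor at a fraction of the dynamic
# range. The floor keeps data-derived thresholds meaningful on (near-)
# noise-free rasters and ties them to signal contrast: with the default
# multipliers the stain threshold lands well above the autofluorescence floor
# but below half the stained-wall contrast.
robust_sd <- function(x, floor_frac = 0.05) {
  max(stats::mad(x), floor_frac * diff(range(x)))
}

# TRUE where angle `ang` (radians) lies within the arc [start, start + extent),
# wrapping at 2*pi. Zero extent matches nothing; extent >= 2*pi matches all.
in_arc <- function(ang, start, extent) {
  if (extent <= 0) return(rep(FALSE, length(ang)))
  if (extent >= 2 * pi) return(rep(TRUE, length(ang)))
  ((ang - start) %% (2 * pi)) <= extent
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
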