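# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  force(code)
}

# Fixed offsets expanding one global seed into independent per-generator
# substreams (keeps every generator reproducible yet decoupled).
.substream_offsets <- c(
  isotopomer = 101L, sweeps = 211L, psc = 307L,
  startle = 401L, track = 503L, qpcr = 601L
)

substream_seed <- function(truth, stream) {
  off <- .substream_offsets[[stream]]
  (as.integer(truth$seed) + off) %% .Machine$integer.max
}

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("`%s` must be a finite %s number", name,
                 if (strict) "strictly positive" else "nonnegative"),
         call. = FALSE)
  }
  invisible(x)
}

# Centered moving-average smoother; ends padded by shrinking the window.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  na <- which(is.na(sm))
  sm[na] <- x[na]
  sm
}

# Reflect coordinates into [lo, hi] (billiard unfolding of a free path).
fold_interval <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  lo + ifelse(y > L, 2 * L - y, y)
}
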