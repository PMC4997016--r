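# Internal helpers shared across modules.

# Derive deterministic child seeds from one root seed. Keeps every stream
# reproducible from a single integer while decorrelating trajectories.
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under a local RNG stream seeded with `seed` (NULL = use the
# current stream). The caller's RNG state is untouched when a seed is given.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Pseudo-logarithmic integer lag grid: <= n_lags unique multiples of the frame
# interval between 1 and k_max, denser at short lags.
pseudolog_lags <- function(k_max, n_lags = 30L) {
  stopifnot(k_max >= 1)
  if (k_max <= n_lags) return(seq_len(k_max))
  ks <- unique(round(exp(seq(0, log(k_max), length.out = n_lags))))
  ks[ks >= 1 & ks <= k_max]
}

# Centered moving average; returns NA where the window is not fully defined.
moving_average <- function(x, width) {
  stopifnot(width >= 1)
  if (width == 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (strict && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  }
  if (!strict && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  invisible(x)
}
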