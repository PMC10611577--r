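# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is restored afterwards so generators never perturb user code.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a per-unit sub-seed from a base seed, kept inside 32-bit integer range
subSeed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * k) %% .Machine$integer.max)
}

stopIf <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

# flatten voxel indices of a logical 3-D array
maskIndices <- function(mask) which(as.logical(mask))

# Pearson correlation between two vectors with explicit degeneracy handling
safeCor <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  stats::cor(a, b)
}

# atanh with |r| capped just inside (-1, 1)
fisherZ <- function(r, cap = 1 - 1e-7) {
  atanh(pmax(pmin(r, cap), -cap))
}

# linear detrend of the columns of a T x V matrix (intercept + linear term)
detrendColumns <- function(Y) {
  tt <- seq_len(nrow(Y))
  X <- cbind(1, tt - mean(tt))
  Y - X %*% qr.coef(qr(X), Y)
}
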