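# Internal helpers: seed derivation, RNG scoping, assertions.

# Derive a reproducible child seed from a master seed and a stage tag, so that
# pipeline stages (pedigree, genotypes, phenotypes, ...) can be rerun
# independently of each other. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- rlang::hash(list(as.integer(seed), as.character(tag)))
  (strtoi(substr(h, 1L, 7L), base = 16L) + as.integer(seed)) %% 2147483647L
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Symmetric matrix check used by relationship-matrix consumers.
check_square_named <- function(m, name) {
  if (!is.matrix(m) && !inherits(m, "Matrix")) {
    abort(sprintf("`%s` must be a matrix", name))
  }
  if (nrow(m) != ncol(m) || is.null(rownames(m))) {
    abort(sprintf("`%s` must be square with animal ids as dimnames", name))
  }
  invisible(m)
}
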