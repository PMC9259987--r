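# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream. seed = NULL evaluates in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (!allow_inf && !is.finite(x))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  if (strict_lower) {
    if (x <= lower)
      stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  if (x < lower)
    stop(sprintf("'%s' must be >= %d", name, lower), call. = FALSE)
  invisible(as.integer(x))
}

as_numeric_matrix <- function(x, name = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  x
}

# Number of flattened parameters (layer-major, weights before biases).
n_flat_params <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Flatten a layer-list of gradients/parameters into one vector
# (layer-major; each weight matrix column-major, then its bias).
flatten_params <- function(params) {
  unlist(lapply(params, function(l) c(as.numeric(l$W), as.numeric(l$b))),
         use.names = FALSE)
}

# Inverse of flatten_params given a template with the right shapes.
unflatten_params <- function(flat, template) {
  out <- template
  pos <- 0L
  for (l in seq_along(template)) {
    nw <- length(template[[l]]$W)
    nb <- length(template[[l]]$b)
    out[[l]]$W <- matrix(flat[pos + seq_len(nw)],
                         nrow = nrow(template[[l]]$W))
    out[[l]]$b <- flat[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  out
}
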