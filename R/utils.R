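# internal helpers shared across modules

# derive a child seed from a user seed; keeps every stream below 2^31
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 7919 * as.double(offset)) %% 2147483647)
}

# coerce a counts/expression input to a base dense matrix when small enough,
# keeping dimnames; sparse inputs stay sparse
as_expr_matrix <- function(x, arg = "x") {
  if (inherits(x, "Matrix") || is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort(sprintf("`%s` must carry row and column names", arg))
    }
    return(x)
  }
  abort(sprintf("`%s` must be a matrix or Matrix, not %s", arg, class(x)[1]))
}

# equal-frequency bin assignment; ties fall in the lower bin via rank order
equal_freq_bins <- function(x, n_bins) {
  stopifnot(n_bins >= 1)
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r / length(x) * n_bins))
}

# mean silhouette width for points (rows) under integer cluster labels
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(unique(labels)) < 2L || n < 3L) return(0)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else return(0)
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

`%1%` <- function(x, default) if (length(x) == 0L) default else x
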