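# Shared fixtures and independent oracles used across test files.

# A small, fast synthetic tree (low resolution keeps the suite quick).
quick_spec <- function(seed = 1, dpi = 100, ...) {
  args <- list(...)
  defaults <- list(crown_semi_axes_cm = c(3, 2.4), crown_jitter = 0.04,
                   trunk_top_cm = 1.4, trunk_bottom_cm = 1.7,
                   trunk_height_cm = 6, dpi = dpi, seed = seed)
  defaults[names(args)] <- args
  do.call(synthetic_tree_spec, defaults)
}

render_to_png <- function(spec, dir = tempdir()) {
  out <- render_tree(spec)
  path <- tempfile(tmpdir = dir, fileext = ".png")
  write_image(out$image, path)
  list(path = path, out = out)
}

as_ink_mask <- function(m) {
  treedraw:::ink_mask(m > 0)
}

# Brute-force Mann-Whitney: permutation distribution of U over all group
# assignments, two-sided doubling rule.
mw_enum_p <- function(x, y) {
  m <- length(x)
  pool <- c(x, y)
  comb <- utils::combn(length(pool), m)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  us <- apply(comb, 2, function(ix) u_of(pool[ix], pool[-ix]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Brute-force Spearman: all n! pairings, two-sided on |rho|.
sp_enum_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  r_obs <- stats::cor(rank(x), rank(y))
  rs <- vapply(perms(seq_along(y)), function(p)
    stats::cor(rank(x), rank(y)[p]), numeric(1))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# Vectorized Monte-Carlo power of the two-sample pooled t-test.
mc_power <- function(n, d, reps = 10000, alpha = 0.05, seed = 11) {
  set.seed(seed)
  x <- matrix(rnorm(n * reps, mean = d), n)
  y <- matrix(rnorm(n * reps), n)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- colSums((x - rep(mx, each = n))^2)
  vy <- colSums((y - rep(my, each = n))^2)
  sp <- sqrt((vx + vy) / (2 * n - 2))
  tt <- (mx - my) / (sp * sqrt(2 / n))
  mean(abs(tt) > qt(1 - alpha / 2, 2 * n - 2))
}
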