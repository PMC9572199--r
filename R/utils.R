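# internal geometry helpers

clamp01 <- function(x) pmin(pmax(x, 0), 1)

vnorm <- function(m) {
  if (is.null(dim(m))) sqrt(sum(m^2)) else sqrt(rowSums(m^2))
}

unitv <- function(v) v / sqrt(sum(v^2))

# angle (degrees) at vertex b for rows of a, b, c (n x 3 matrices)
angle_deg <- function(a, b, c) {
  u <- a - b
  w <- c - b
  cosang <- rowSums(u * w) / (vnorm(u) * vnorm(w))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# all pairwise distances between rows of x (n x 3) and y (m x 3)
cross_dist <- function(x, y) {
  x2 <- rowSums(x^2)
  y2 <- rowSums(y^2)
  d2 <- outer(x2, y2, "+") - 2 * tcrossprod(x, y)
  sqrt(pmax(d2, 0))
}

# population standard deviation (divides by n, not n - 1)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
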