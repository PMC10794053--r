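# Shared fixtures and independent oracles for the test suite.

# --- tiny annotation builders -------------------------------------------

fixPoints <- function(xy, width = 100, height = 100, id = "fix") {
  pointAnnotation(id, width, height, xy)
}

fixBoxes <- function(df, id = "fix") boxAnnotation(id, df)

# write a minimal Pascal-VOC XML by hand (independent of writeVocBoxes)
writeRawVoc <- function(path, objects) {
  lines <- c("<annotation>", "  <filename>fix</filename>")
  for (ob in objects) {
    lines <- c(lines, "  <object>",
               sprintf("    <name>%s</name>", ob$name %||% "tree"),
               "    <bndbox>")
    for (tag in c("xmin", "ymin", "xmax", "ymax"))
      if (!is.null(ob[[tag]]))
        lines <- c(lines, sprintf("      <%s>%s</%s>", tag, ob[[tag]], tag))
    lines <- c(lines, "    </bndbox>", "  </object>")
  }
  writeLines(c(lines, "</annotation>"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent UOT oracles --------------------------------------------

# objective exactly as specified, recomputed in R
uotObjectiveR <- function(P, C, a, b, eps, tau) {
  plogp <- sum(ifelse(P > 0, P * log(P), 0))
  sum(C * P) - eps * plogp +
    tau * sum((rowSums(P) - a)^2) + tau * sum(abs(colSums(P) - b))
}

# brute-force/convex oracle for n*m <= 9: multi-start box-constrained BFGS
# on the flattened plan (independent of the package's solver)
uotOracleOptim <- function(C, a, b, eps, tau) {
  n <- length(a); m <- length(b)
  fl <- function(p) uotObjectiveR(matrix(p, n, m), C, a, b, eps, tau)
  starts <- list(rep(0.01, n * m), rep(1 / (n * m), n * m),
                 as.numeric(outer(a, b)) / max(sum(b), 1e-9) + 1e-3,
                 rep(2 / (n * m), n * m))
  best <- Inf
  for (s in starts) {
    r <- stats::optim(s, fl, method = "L-BFGS-B", lower = 1e-9, upper = 10,
                      control = list(maxit = 2000, factr = 1e4))
    best <- min(best, r$value)
  }
  best
}

# exact balanced optimal transport via the simplex LP (boot package)
balancedOTLP <- function(C, a, b) {
  n <- length(a); m <- length(b)
  A3 <- NULL; b3 <- NULL
  for (i in seq_len(n)) {
    v <- matrix(0, n, m); v[i, ] <- 1
    A3 <- rbind(A3, as.numeric(v)); b3 <- c(b3, a[i])
  }
  for (j in seq_len(m - 1)) {   # last column constraint is redundant
    v <- matrix(0, n, m); v[, j] <- 1
    A3 <- rbind(A3, as.numeric(v)); b3 <- c(b3, b[j])
  }
  r <- boot::simplex(a = as.numeric(C), A3 = A3, b3 = b3, maxi = FALSE)
  r$value
}

# random small UOT instance
randomUotInstance <- function(maxDim = 3L) {
  n <- sample(seq_len(maxDim), 1)
  m <- sample(seq_len(maxDim), 1)
  list(a = stats::runif(n, 0, 2), b = stats::runif(m, 0.2, 2),
       C = matrix(stats::runif(n * m, 0.1, 3), n, m))
}
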