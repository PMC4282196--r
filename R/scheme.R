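# Diffusion gradient schemes: b-values plus unit direction vectors, the
# encoding of the acquisition's diffusion sensitisation.

#' Build a multi-shell gradient scheme
#'
#' Constructs an acquisition scheme with one `b = 0` volume plus
#' `n_dirs_per_shell` unit direction vectors replicated on each nonzero
#' b-value shell. Directions are laid out quasi-uniformly on the sphere by
#' electrostatic repulsion of antipodally symmetric point pairs and are
#' deterministic for a fixed `seed`.
#'
#' The default reproduces the acquisition the package emulates: b = 0, 1000
#' and 2000 s/mm^2 with 25 nonparallel directions per nonzero shell
#' (51 volumes).
#'
#' @param n_dirs_per_shell number of unique directions (>= 6; >= 15 across
#'   two nonzero shells is needed for a full kurtosis fit).
#' @param bvals b-values in s/mm^2; must include 0.
#' @param seed integer seed for the repulsion layout.
#' @return an object of class `gradient_scheme`: list with `bvals`
#'   (length-nvol vector), `bvecs` (nvol x 3 matrix, zero rows where b = 0)
#'   and `dirs` (the unique directions).
#' @examples
#' sch <- gradient_scheme(25, c(0, 1000, 2000))
#' length(sch$bvals)  # 51
#' @export
gradient_scheme <- function(n_dirs_per_shell = 25L, bvals = c(0, 1000, 2000),
                            seed = 1234L) {
  if (n_dirs_per_shell < 6L)
    stop("invalid scheme: fewer than 6 directions cannot determine a diffusion tensor")
  if (!any(bvals == 0)) stop("invalid scheme: bvals must include b = 0")
  if (any(bvals < 0)) stop("invalid scheme: negative b-values")
  shells <- sort(unique(bvals[bvals > 0]))
  dirs <- repulsion_dirs(n_dirs_per_shell, seed = seed)
  b <- c(0, rep(shells, each = n_dirs_per_shell))
  v <- rbind(c(0, 0, 0), dirs[rep(seq_len(n_dirs_per_shell), length(shells)), , drop = FALSE])
  structure(list(bvals = b, bvecs = unname(v), dirs = unname(dirs)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  shells <- sort(unique(x$bvals[x$bvals > 0]))
  cat("Gradient scheme:", length(x$bvals), "volumes;",
      sum(x$bvals == 0), "b=0;", nrow(x$dirs), "directions on shells b =",
      paste(shells, collapse = ", "), "s/mm^2\n")
  invisible(x)
}

# Quasi-uniform antipodally-symmetric direction set by electrostatic
# repulsion: pairwise 1/r^2 forces between each point and both poles of every
# other point, projected onto the sphere each step.
repulsion_dirs <- function(n, seed = 1234L, n_iter = 400L, step = 0.02) {
  with_seed(seed, {
    x <- matrix(rnorm(3 * n), n, 3)
  })
  x <- x / sqrt(rowSums(x^2))
  for (it in seq_len(n_iter)) {
    f <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(x[-i, , drop = FALSE], 2, x[i, ], function(a, b) b - a)
      d2 <- sweep(-x[-i, , drop = FALSE], 2, x[i, ], function(a, b) b - a)
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
      f[i, ] <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    x <- x + step * f
    x <- x / sqrt(rowSums(x^2))
  }
  x
}

# Deterministic quasi-uniform direction set on the full sphere (Fibonacci
# spiral); used as the dense quadrature option for the MK average.
fibonacci_sphere <- function(n = 321L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

validate_scheme <- function(scheme, for_kurtosis = TRUE) {
  stopifnot(inherits(scheme, "gradient_scheme") || is.list(scheme))
  b <- scheme$bvals
  v <- scheme$bvecs
  if (any(b < 0)) stop("invalid scheme: negative b-values")
  if (!any(b == 0)) stop("invalid scheme: no b = 0 volume")
  nz <- b > 0
  nrm <- sqrt(rowSums(v[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("invalid scheme: nonzero-b direction norms must be 1")
  if (for_kurtosis) {
    ud <- unique(round(v[nz, , drop = FALSE], 6))
    if (nrow(ud) < 15L || length(unique(b[nz])) < 2L)
      stop("invalid scheme: a kurtosis fit needs >= 15 unique directions on >= 2 nonzero shells")
  }
  invisible(TRUE)
}

#' Read and write FSL-style gradient tables
#'
#' `read_scheme()` reads `bvals`/`bvecs` text files (one row of b-values and
#' three rows of direction components); `write_scheme()` writes them.
#'
#' @param bvals_file,bvecs_file paths to the two text files.
#' @param scheme a `gradient_scheme`.
#' @return `read_scheme()` returns a `gradient_scheme`.
#' @export
read_scheme <- function(bvals_file, bvecs_file) {
  b <- scan(bvals_file, quiet = TRUE)
  v <- as.matrix(read.table(bvecs_file))
  if (nrow(v) != 3L) stop("bvecs file must have 3 rows")
  v <- t(v)
  if (length(b) != nrow(v)) stop("bvals and bvecs disagree on volume count")
  dirs <- unique(round(v[b > 0, , drop = FALSE], 6))
  structure(list(bvals = b, bvecs = unname(v), dirs = dirs),
            class = "gradient_scheme")
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, bvals_file, bvecs_file) {
  cat(paste(scheme$bvals, collapse = " "), "\n", file = bvals_file)
  write.table(format(t(scheme$bvecs), digits = 8), bvecs_file,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(NULL)
}
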