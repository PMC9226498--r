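# Small fixtures built in code; nothing is stored on disk.

shift_tsv_lines <- function(rows) {
  c("residue\taa\tatom\tshift_ppm", rows)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A tiny fixed-column PDB: 3 residues x 2 atoms, all B-factors 11.11
tiny_pdb_lines <- function() {
  fmt <- "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s"
  lines <- character(0)
  serial <- 0L
  for (res in 1:3) {
    for (at in c("N", "CA")) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, at, "ALA", res,
                                res * 1.0, res * 2.0, res * 3.0, 1.00, 11.11,
                                substr(at, 1, 1)))
    }
  }
  c(lines, "TER", "END")
}

# Brute-force equilibrium: [PL] as the numeric root of (P-x)(L-x) = Kd*x,
# bracketing root polished to machine precision by Newton iteration
fb_bruteforce <- function(p, l, kd) {
  if (l == 0) return(0)
  f <- function(x) (p - x) * (l - x) - kd * x
  x <- stats::uniroot(f, c(0, min(p, l)), tol = .Machine$double.eps)$root
  for (i in 1:8) {
    fp <- 2 * x - (p + l + kd)
    x <- x - f(x) / fp
    x <- min(max(x, 0), min(p, l))
  }
  x / p
}

# Brute-force TLS collinearity: minimise max-perp over line angle is not the
# contract; the oracle refits the TLS line by 1-D optimisation over its
# angle (minimising the sum of squared perpendicular distances) and then
# takes the maximum perpendicular distance.
max_perp_bruteforce <- function(h, n, alpha) {
  x <- h - mean(h)
  y <- alpha * n - mean(alpha * n)
  sse <- function(theta) {
    d <- -sin(theta) * x + cos(theta) * y
    sum(d^2)
  }
  grid <- seq(0, pi, length.out = 3601L)
  best <- grid[which.min(vapply(grid, sse, numeric(1)))]
  opt <- stats::optimize(sse, c(best - 0.01, best + 0.01), tol = 1e-14)
  theta <- opt$minimum
  max(abs(-sin(theta) * x + cos(theta) * y))
}

small_titration_spec <- function(seed, kd = 2e-4, noise_sd_h = 0.004,
                                 noise_sd_n = 0.02, n_residues = 12L) {
  clamp_like_titration_spec(seed, kd = kd, noise_sd_h = noise_sd_h,
                            noise_sd_n = noise_sd_n,
                            n_residues = n_residues, first_residue = 140L)
}
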