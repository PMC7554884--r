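# Small numeric helpers shared across modules.

# Atomic masses in Da for the elements this package expects to meet in
# protein/water/ligand PDB files. COM computation needs masses; PDB lacks them.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  SE = 78.971, B = 10.81, NA. = 22.990, MG = 24.305, K = 39.098,
  CA = 40.078, ZN = 65.38, FE = 55.845, MN = 54.938
)

#' Atomic mass lookup
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in Da.
#' @export
atomic_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  m <- .element_masses[key]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("no mass tabulated for element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

# Round half away from zero (Table print convention); base round() is
# round-half-even and would turn e.g. 0.25 into 0.2.
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All fixture randomness flows through this.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
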