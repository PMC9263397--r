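# fixtures built in code: tiny images, masks and series with known structure

# bold4d from a t x V matrix laid out along the x axis of a V x 1 x 1 grid
bold_from_matrix <- function(m, tr = 2) {
  nt <- nrow(m)
  v <- ncol(m)
  bold4d(array(t(m), dim = c(v, 1, 1, nt)), tr = tr)
}

# full mask over a V x 1 x 1 grid
line_mask <- function(v) {
  make_gm_mask(array(1, dim = c(v, 1, 1)), threshold = 0.2)
}

# centred series of unit L2 norm
unitize <- function(x) {
  x <- x - mean(x)
  x / sqrt(sum(x^2))
}

# pair of series with exact sample correlation rho
correlated_pair <- function(nt, rho, seed = 1) {
  set.seed(seed)
  x <- unitize(rnorm(nt))
  e <- rnorm(nt)
  e <- e - mean(e)
  e <- unitize(e - x * sum(e * x))
  y <- rho * x + sqrt(1 - rho^2) * e
  cbind(x, y)
}

# small cohort config for pipeline-level tests
small_cohort_config <- function(seed = 1, n_per_group = c(10L, 10L, 10L),
                                n_volumes = 60L, delta = 0.5, ...) {
  cohort_config(
    n_per_group = n_per_group, n_volumes = n_volumes,
    effect_regions = if (delta == 0) NULL else default_effect_regions(delta),
    seed = seed, ...)
}

# subject table + null GFC stack on a V x 1 x 1 grid for design-level tests
null_stack <- function(n = 30, v = 50, seed = 1) {
  set.seed(seed)
  subjects <- tibble::tibble(
    id = sprintf("s%02d", 1:n),
    group = rep(c("S1", "S0", "HC"), length.out = n),
    age = rnorm(n, 30, 5),
    gender = sample(c("male", "female"), n, replace = TRUE),
    education_years = rnorm(n, 14, 3),
    mean_fd = abs(rnorm(n, 0.1, 0.03)))
  prob <- array(1, dim = c(v, 1, 1))
  mask <- make_gm_mask(prob, 0.2)
  list(Y = matrix(rnorm(n * v), n, v),
       vox = which(mask$mask, arr.ind = TRUE),
       mask = mask, affine = diag(4), subjects = subjects)
}
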