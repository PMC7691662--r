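# shared fixtures, all generated in code

# small cohort for fast structural tests; overrides win over the defaults
small_config <- function(...) {
  args <- utils::modifyList(list(
    n_subjects = 80,
    n_features_per_group = c(demographic = 6, anthropometric = 6,
                             blood = 8, oct = 6, dietary = 30),
    dietary_mix = c(continuous = 14, discrete = 10, multi_choice = 6),
    effect_sizes = c(age = -0.15, blood_hdl = 0.12, diet_intake_001 = 0.18)
  ), list(...))
  do.call(sim_config, args)
}

# full-size cohort but a lean feature panel; default noise regime
lean_config <- function(...) {
  args <- utils::modifyList(list(
    n_features_per_group = c(demographic = 6, anthropometric = 10,
                             blood = 10, oct = 8, dietary = 40),
    dietary_mix = c(continuous = 20, discrete = 14, multi_choice = 6)
  ), list(...))
  do.call(sim_config, args)
}

# planted regression design: k equally informative features, target R^2
planted_design <- function(n, p, k = 5, r2 = 0.5, seed = 1,
                           signal = c("linear", "step")) {
  signal <- match.arg(signal)
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%03d", seq_len(n)),
                                paste0("f", seq_len(p))))
    s <- if (signal == "linear") rowSums(x[, seq_len(k), drop = FALSE])
         else rowSums(x[, seq_len(k), drop = FALSE] > 0) # tree-friendly steps
    s <- as.numeric(s)
    noise_sd <- sd(s) * sqrt((1 - r2) / r2)
    y <- s + rnorm(n, 0, noise_sd)
    list(x = x, y = y, informative = paste0("f", seq_len(k)),
         signal = s, ceiling = cor(s, y))
  })
}

# toy schema used across preprocessing tests
toy_schema <- function() {
  feature_schema(tibble::tibble(
    name = c("weight", "height", "smoker", "ffq_greens"),
    kind = c("continuous", "continuous", "discrete", "multi_choice"),
    group = c("anthropometric", "anthropometric", "demographic", "dietary"),
    min = c(30, 100, NA, NA),
    max = c(200, 250, NA, NA),
    options = list(NULL, NULL, c("no", "yes"), c("egg", "spinach", "kale"))
  ))
}

toy_table <- function() {
  tibble::tibble(
    subject_id = sprintf("T%02d", 1:4),
    weight = c(70, 1640, 55, 82),
    height = c(170, 160, 150, 180),
    smoker = c("no", "yes", "maybe", "no"),
    ffq_greens = c("egg;kale", "", "spinach", "egg;plastic")
  )
}
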