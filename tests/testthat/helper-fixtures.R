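# Shared fixtures, built once per test run and memoised. Scenes here are
# deliberately small (170 px) so stacks and trainings stay fast; the
# acceptance tests use the full-size defaults.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_spec <- function() {
  scene_spec(height = 170, width = 170, blob_count_range = c(8, 16),
             blob_radius_range = c(4, 9), foreground_fraction_target = 0.04)
}

shared_dataset <- function() {
  memo("dataset", function() {
    make_dataset(4, small_spec(), patches_per_image = 6, seed = 42)
  })
}

# a trained model for qualitative checks (valid distributions, level
# ordering, robustness plumbing). When the full acceptance study has
# already been built in this session its model is reused; otherwise a
# small quick training stands in.
shared_model <- function() {
  if (exists("acceptance_study", envir = .fixture_cache)) {
    return(get("acceptance_study", envir = .fixture_cache)$model)
  }
  memo("model", function() {
    train_focus_model(shared_dataset()$train,
                      cfg = desk_train_config(steps = 250, batch_size = 16,
                                              seed = 5))
  })
}

# the 10 defocus kernels for the default optics, shared across files
shared_kernels <- function() {
  memo("kernels", function() {
    p <- optical_params()
    lapply(1:10, function(L) compute_psf(p, 2 * L))
  })
}

# one full-size scene + defocus stack for PLLS/stack property tests
shared_stack <- function() {
  memo("stack", function() {
    sc <- make_scene(scene_spec(), seed = 3)
    st <- generate_defocus_stack(sc$image, optical_params(), sensor_model(),
                                 seed = 11, kernels = shared_kernels())
    list(scene = sc, stack = st)
  })
}

random_distribution <- function(n = 11) {
  p <- stats::rexp(n)
  p / sum(p)
}

# synthesize an image whose radial amplitude spectrum is a pure power law
# f^(alpha/2), i.e. power spectral density proportional to f^alpha
power_law_image <- function(n, alpha, seed) {
  withr::with_seed(seed, {
    wn <- matrix(stats::rnorm(n * n), n, n)
  })
  fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  f <- sqrt(outer(fr^2, fr^2, "+"))
  amp <- ifelse(f > 0, f^(alpha / 2), 0)
  Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / (n * n)
}

# brute-force oracle: try every achievable split of the score axis and
# return the best validation F-score
oracle_best_f <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(min(s) - 1, s, (s[-1] + s[-length(s)]) / 2, max(s) + 1)
  f <- function(th) {
    pred <- as.integer(scores >= th)
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    if (tp == 0) return(0)
    pr <- tp / (tp + fp); rc <- tp / (tp + fn)
    2 * pr * rc / (pr + rc)
  }
  max(vapply(cand, f, numeric(1)))
}

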