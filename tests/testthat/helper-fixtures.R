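# Session-shared fixtures: datasets are generated once per test run and
# reused across test files.

.fixture_env <- new.env(parent = emptyenv())

shared_dataset <- function(cue = "color", n_images = 160L, seed = 11L,
                           p_monomer = 0.5, scenario = "full") {
  key <- paste(cue, n_images, seed, p_monomer, scenario, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("cnat_ds_", key))
    cfg <- synth_config(out_dir = dir, n_images = n_images, seed = seed,
                        cue = cue, p_monomer = p_monomer,
                        scenario = scenario)
    .fixture_env[[key]] <- generate_dataset(cfg)
  }
  .fixture_env[[key]]
}

rand_fm <- function(h, w, c, n = 1L, seed = NULL, sd = 1) {
  gen <- function() array(stats::rnorm(h * w * c * n, sd = sd), c(h, w, c, n))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# finite-difference gradient check used by test-gradients.R
fd_gradcheck <- function(make, h = 6, w = 6, cin = 4, n = 2, eps = 1e-5,
                         n_params = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- make()
    x <- array(stats::rnorm(h * w * cin * n), c(h, w, cin, n))
    y0 <- forward(m, x, training = TRUE)
    wts <- array(stats::rnorm(length(y0)),
                 dim = if (is.null(dim(y0))) length(y0) else dim(y0))
    loss <- function() sum(forward(m, x, training = TRUE) * wts)
    cnatnet:::zero_grad(m)
    y <- forward(m, x, training = TRUE)
    dx <- cnatnet:::backward(m, array(wts, dim = dim(y)))
    ps <- cnatnet:::parameters(m)
    maxerr <- 0
    sel <- unique(round(seq(1, length(ps),
                            length.out = min(n_params, length(ps)))))
    for (p in ps[sel]) {
      mod <- p$module; f <- p$field
      idx <- sample(length(mod[[f]]), min(3, length(mod[[f]])))
      for (i in idx) {
        th0 <- mod[[f]][i]
        mod[[f]][i] <- th0 + eps; lp <- loss()
        mod[[f]][i] <- th0 - eps; lm <- loss()
        mod[[f]][i] <- th0
        g_an <- mod[[cnatnet:::grad_field(f)]][i]
        maxerr <- max(maxerr, abs((lp - lm) / (2 * eps) - g_an) /
                        max(1, abs(g_an)))
      }
    }
    for (i in sample(length(x), 4)) {
      x0 <- x[i]
      x[i] <- x0 + eps; lp <- loss()
      x[i] <- x0 - eps; lm <- loss()
      x[i] <- x0
      maxerr <- max(maxerr, abs((lp - lm) / (2 * eps) - dx[i]) /
                      max(1, abs(dx[i])))
    }
    maxerr
  })
}
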