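# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_core <- function(seed = 7, ...) {
  memo(paste0("core", seed), generate_tma_core(
    scene_params(width = 380, height = 380, n_melanoma = 30, n_other = 30,
                 seed = seed, ...)))
}

# Greedy one-to-one matching of truth nuclei to detected centroids; returns
# per-truth-nucleus distance (Inf when no unclaimed object within reach).
match_truth <- function(truth, detected, max_dist = 2.5) {
  claimed <- rep(FALSE, nrow(detected))
  d_out <- rep(Inf, nrow(truth))
  for (i in order(truth$x)) {
    d <- sqrt((detected$x - truth$x[i])^2 + (detected$y - truth$y[i])^2)
    d[claimed] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= max_dist) {
      claimed[j] <- TRUE
      d_out[i] <- d[j]
    }
  }
  d_out
}

# Gaussian feature-level benchmark: n per class, p features of which the
# first n_informative carry a mean shift of `effect` SDs.
simulated_dataset <- function(n = 500, p = 10, n_informative = 5,
                              effect = 1.5, seed = 1) {
  melmark:::with_seed(seed, {
    x <- matrix(rnorm(2 * n * p), 2 * n, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    y <- factor(rep(c("melanoma", "other"), each = n),
                levels = c("melanoma", "other"))
    if (n_informative > 0) {
      x[y == "melanoma", seq_len(n_informative)] <-
        x[y == "melanoma", seq_len(n_informative)] + effect
    }
    cell_dataset(x, y)
  })
}

# Marker-guided end-to-end run on the separable preset (2,000 nuclei per
# class over 10 cores, 2 cores held out); memoized because both the core
# learning check and the biomarker scoring check use its model.
marker_guided_run <- function() {
  memo("marker_run", {
    scenes <- lapply(1:10, function(i) {
      generate_tma_core(scene_params(width = 660, height = 660,
                                     n_melanoma = 200, n_other = 200,
                                     seed = 9000 + i))
    })
    cfg <- pipeline_config(holdout = c(9, 10), seed = 77)
    run_training_pipeline(scenes, cfg)
  })
}
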