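#' Specification for a planted-feature synthetic dataset
#'
#' Emulates the structure of an active/decoy compound screen: m active
#' rows plus `decoy_ratio * m` decoy rows over a fused-style feature
#' space of `d - n_real_cols` binary fingerprint-like columns followed
#' by `n_real_cols` descriptor-like real columns. `n_informative`
#' columns (drawn across both spans) separate the classes: informative
#' binary columns fire with `active_rate` in actives vs `decoy_rate` in
#' decoys, background binary columns with `background_rate` everywhere;
#' informative real columns are Normal(`effect_shift`, 1) in actives vs
#' Normal(0, 1) in decoys, background real columns Normal(0, 1) for all.
#'
#' @param m number of active compounds (default 94).
#' @param decoy_ratio decoys per active (default 3).
#' @param d total feature count (default 500; use
#'   [planted_spec_fullwidth()] for the 2423-wide profile).
#' @param n_informative planted class-informative columns (default 20).
#' @param active_rate,decoy_rate,background_rate Bernoulli on-rates
#'   (defaults 0.6, 0.2, 0.1).
#' @param n_real_cols trailing real-valued columns (default 40).
#' @param effect_shift mean shift of informative real columns in
#'   actives (default 1).
#' @param seed integer seed.
#' @return a `planted_spec` object.
#' @export
planted_spec <- function(m = 94L, decoy_ratio = 3L, d = 500L,
                         n_informative = 20L, active_rate = 0.6,
                         decoy_rate = 0.2, background_rate = 0.1,
                         n_real_cols = 40L, effect_shift = 1.0, seed = 1L) {
  rates <- c(active_rate, decoy_rate, background_rate)
  if (any(rates < 0 | rates > 1)) {
    stop_forgenet("rates must lie in [0,1]", "forgenet_input_error")
  }
  if (n_informative > d) {
    stop_forgenet("n_informative must not exceed d", "forgenet_input_error")
  }
  if (decoy_ratio < 1) {
    stop_forgenet("decoy_ratio must be >= 1", "forgenet_input_error")
  }
  if (n_real_cols > d) {
    stop_forgenet("n_real_cols must not exceed d", "forgenet_input_error")
  }
  structure(list(m = as.integer(m), decoy_ratio = as.integer(decoy_ratio),
                 d = as.integer(d), n_informative = as.integer(n_informative),
                 active_rate = active_rate, decoy_rate = decoy_rate,
                 background_rate = background_rate,
                 n_real_cols = as.integer(n_real_cols),
                 effect_shift = effect_shift, seed = as.integer(seed)),
            class = "planted_spec")
}

#' Full-width (2423-column) planted profile
#'
#' Same generative model with the real fused layout: 2048 + 167 binary
#' columns and 208 real columns.
#'
#' @param ... overrides passed to [planted_spec()].
#' @return a `planted_spec`.
#' @export
planted_spec_fullwidth <- function(...) {
  args <- utils::modifyList(list(d = 2423L, n_real_cols = 208L,
                                 n_informative = 40L), list(...))
  do.call(planted_spec, args)
}

#' Generate a planted-feature dataset
#'
#' @param spec a `planted_spec`.
#' @return list with `data` (a `fused_features`-style object: matrix,
#'   labels, block spans BINARY/REAL) and `informative` (ground-truth
#'   1-based column indices).
#' @export
generate_planted <- function(spec = planted_spec()) {
  m <- spec$m; n_neg <- spec$decoy_ratio * m
  n <- m + n_neg
  d <- spec$d
  n_bin <- d - spec$n_real_cols
  with_seed(spec$seed, {
    informative <- sort(sample.int(d, spec$n_informative))
    X <- matrix(0, n, d)
    active <- c(rep(TRUE, m), rep(FALSE, n_neg))
    bin_cols <- seq_len(n_bin)
    real_cols <- if (spec$n_real_cols > 0) (n_bin + 1L):d else integer(0)
    inf_bin <- intersect(informative, bin_cols)
    inf_real <- intersect(informative, real_cols)
    bg_bin <- setdiff(bin_cols, inf_bin)
    bg_real <- setdiff(real_cols, inf_real)
    X[, bg_bin] <- stats::rbinom(n * length(bg_bin), 1, spec$background_rate)
    for (j in inf_bin) {
      X[active, j] <- stats::rbinom(m, 1, spec$active_rate)
      X[!active, j] <- stats::rbinom(n_neg, 1, spec$decoy_rate)
    }
    X[, bg_real] <- stats::rnorm(n * length(bg_real))
    for (j in inf_real) {
      X[, j] <- stats::rnorm(n, mean = ifelse(active, spec$effect_shift, 0))
    }
    labels <- ifelse(active, 1L, -1L)
    rownames(X) <- c(sprintf("active_%03d", seq_len(m)),
                     sprintf("decoy_%03d", seq_len(n_neg)))
    colnames(X) <- c(sprintf("bin_%04d", seq_len(n_bin)),
                     if (spec$n_real_cols > 0) sprintf("real_%03d", seq_len(spec$n_real_cols)))
    blocks <- data.frame(
      name = c("BINARY", "REAL"),
      start = c(1L, n_bin + 1L),
      end = c(n_bin, d), stringsAsFactors = FALSE)
    data <- structure(list(matrix = X, blocks = blocks,
                           labels = labels, rdkit_stats = NULL),
                      class = "fused_features")
    list(data = data, informative = informative)
  })
}

#' Sample decoys without replacement
#'
#' Implements the 3-per-active selection rule: draws exactly
#' `ratio * m` distinct records uniformly without replacement from the
#' decoy pool.
#'
#' @param pool matrix or data.frame of candidate decoy records (rows).
#' @param m number of actives.
#' @param ratio decoys per active (default 3).
#' @param seed integer seed.
#' @return the sampled subset of `pool` rows (same type as `pool`).
#' @export
sample_decoys <- function(pool, m, ratio = 3L, seed = 1L) {
  n_pool <- nrow(pool)
  need <- ratio * m
  if (n_pool < need) {
    stop_forgenet(sprintf("decoy pool too small: need %d, have %d",
                          need, n_pool),
                  "forgenet_input_error")
  }
  idx <- with_seed(seed, sample.int(n_pool, need, replace = FALSE))
  pool[idx, , drop = FALSE]
}

#' Fixture compound records
#'
#' A small in-repo list of named, publicly known actives (flavonoids
#' and phytosterols reported as Alzheimer-related actives) and
#' unrelated inactive compounds, with canonical SMILES. These are test
#' fixtures for featurization round-trips, not a reconstruction of any
#' screening dataset.
#'
#' @return data.frame with columns id, smiles, label (+1/-1).
#' @export
fixture_compounds <- function() {
  read_compounds(system.file("extdata", "fixture_compounds.csv",
                             package = "forgenet", mustWork = TRUE))
}

#' Write a planted dataset in the external input schemas
#'
#' Emits the feature TSV (+ JSON manifest) exactly as
#' [write_features()] does for real data, so simulated files are
#' interchangeable with featurized ones.
#'
#' @param planted result of [generate_planted()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_planted <- function(planted, path) {
  write_features(planted$data, path)
  invisible(path)
}
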