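# Shared fixtures, built in code. The teacher task is the noiseless
# realizable recovery problem: targets come from the fixed teacher network,
# split 70/15/15 by energy stratum.
.task_cache <- new.env(parent = emptyenv())

teacher_task <- function(n = 150, seed = 42) {
  key <- sprintf("task_%d_%d", n, seed)
  if (is.null(.task_cache[[key]])) {
    mols <- simulate_qspr(n = n, noise_sd = 0, teacher = "network", seed = seed)
    mols <- stratified_split(mols, split_spec(seed = seed))
    .task_cache[[key]] <- list(
      train = dplyr::filter(mols, split == "train"),
      validation = dplyr::filter(mols, split == "validation"),
      test = dplyr::filter(mols, split == "test")
    )
  }
  .task_cache[[key]]
}

# RMSEP on the model's normalized target scale.
norm_rmsep <- function(fit, data) {
  yn <- apply_normalization(data, fit$norm)[[fit$target]]
  pn <- apply_normalization(tibble::tibble(E = predict(fit, data)), fit$norm)$E
  rmsep(yn, pn)
}

# A table whose strata have the published sizes 12/30/33/39/46, with
# energies drawn inside each printed band.
published_strata_table <- function(seed = 1) {
  bands <- list(c(2.69, 2.99), c(3.01, 3.96), c(4.00, 4.68),
                c(4.70, 5.08), c(5.10, 6.66))
  sizes <- c(12, 30, 33, 39, 46)
  withr::with_seed(seed, {
    E <- unlist(purrr::map2(bands, sizes, function(b, n) runif(n, b[1], b[2])))
  })
  tibble::tibble(id = sprintf("m%03d", seq_along(E)), E = E)
}
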