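# Shared fixtures and slow-object cache for the test suite.

.cache <- new.env(parent = emptyenv())

cd64_data <- function() {
  if (is.null(.cache$cd64)) {
    .cache$cd64 <- read_meta_csv(srocpb_example("cd64.csv"))
  }
  .cache$cd64
}

# the unadjusted CD64 fit is used by several tests; compute it once
cd64_fit <- function() {
  if (is.null(.cache$cd64_fit)) {
    .cache$cd64_fit <- fit_unadjusted(cd64_data())
  }
  .cache$cd64_fit
}

# small deterministic synthetic meta-analysis (no RNG at test time)
tiny_meta <- function() {
  tibble::tibble(
    label = paste0("s", 1:8),
    tp = c(18L, 25L, 12L, 30L, 22L, 15L, 27L, 9L),
    fn = c(4L, 6L, 3L, 2L, 7L, 5L, 3L, 6L),
    fp = c(20L, 31L, 15L, 9L, 24L, 18L, 12L, 22L),
    tn = c(180L, 210L, 145L, 160L, 190L, 170L, 200L, 130L)
  )
}

# disease-label reversal: swaps the roles of sensitivity and specificity
transpose_meta <- function(data) {
  tibble::tibble(label = data$label, tp = data$tn, fp = data$fn,
                 fn = data$fp, tn = data$tp)
}
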