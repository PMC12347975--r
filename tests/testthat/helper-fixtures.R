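# random valid lab panels for property-style tests
random_panels <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    glucose = runif(n, 60, 300),
    neutrophil_count = runif(n, 1, 25),
    lymphocyte_count = runif(n, 0.2, 5),
    serum_creatinine = runif(n, 0.3, 3),
    platelets = runif(n, 100, 600),
    neutrophil_pct = runif(n, 40, 95),
    lymphocyte_pct = runif(n, 2, 50)
  ))
}

# the generating three-block structure of the default cohort config
generating_blocks <- function() {
  list(coagulation = c("prothrombin_time", "inr", "aptt"),
       renal_metabolic = c("urea", "serum_creatinine", "glucose"),
       immune = c("neutrophil_count", "lymphocyte_count"))
}

# TRUE when a membership vector assigns each block to one distinct component
memberships_match_blocks <- function(membership) {
  blocks <- generating_blocks()
  per_block <- lapply(blocks, function(b) unique(membership[b]))
  all(lengths(per_block) == 1) &&
    length(unique(unlist(per_block))) == length(blocks)
}

# parameter table with means far from the truncation bound, so that
# law-of-large-numbers checks on the generator are not biased by truncation
high_mean_params <- function() {
  p <- metinflam:::default_lab_params()
  p$m_perf <- pmax(p$m_perf, 8 * p$s_perf)
  p$m_non <- pmax(p$m_non, 8 * p$s_non)
  p$hi <- Inf
  p
}

# brute-force pairwise AUC oracle: P(score_pos > score_neg) + 0.5 P(tie)
pairwise_auc <- function(scores, labels) {
  sp <- scores[labels]; sn <- scores[!labels]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
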