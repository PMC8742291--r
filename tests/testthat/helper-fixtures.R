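# Small in-code fixtures shared across the suite.

# a hand-built cohort with a bit of everything: both groups, both sexes,
# some missing labs, an exact CHOL/HDL identity
tiny_cohort <- function() {
  df <- data.frame(
    ssn_status = c("SSN-", "SSN-", "SSN+", "SSN+"),
    account_number = c("101", "102", "103", "104"),
    gender = c("M", "F", "M", "F"),
    age = c(60, 45, 52, NA),
    race = c("chinese", "other_asian", "chinese", "other"),
    tsh = c(2.0, 1.5, NA, 3.0),
    psa = c(1.1, NA, NA, NA),
    hbsab = c("pos", "neg", "neg", "pos"),
    hbsag = c("neg", "neg", "pos", "neg"),
    glu = c(90, 100, 85, 110),
    chol = c(210, 180, NA, 240),
    tg = c(150, NA, 120, 200),
    hdl = c(52.5, 60, 45, 48),
    ldl = c(120, 100, 130, 150),
    chol_hdl = c(4.0, 3.0, 5.0, 5.0),
    stringsAsFactors = FALSE
  )
  cohort_table(df)
}

# feature_matrix wrapper around a ground-truth low-rank matrix, with a
# chol_hdl column decodable into a plausible ratio range; used to exercise
# the evaluation path on data the factorization can actually reconstruct
lowrank_feature_matrix <- function(n = 100, p = 16, k = 3, seed = 1,
                                   noise_sd = 0) {
  d <- generate_lowrank(n, p, k, noise_sd = noise_sd, seed = seed)
  feats <- c(c("ssn_pos", "ssn_neg", "account_number", "gender", "age",
               "race", "tsh", "psa", "hbsab", "hbsag", "glu", "chol", "tg",
               "hdl", "ldl")[seq_len(p - 1)], "chol_hdl")
  colnames(d$X) <- colnames(d$M) <- feats
  # the ratio column decodes onto a range spanning all four risk bands
  scaling <- stats::setNames(lapply(feats, function(f) {
    list(kind = "continuous", offset = 1.0,
         scale = if (f == "chol_hdl") 2.5 else 1.0)
  }), feats)
  fm <- structure(list(X = d$X, M = d$M, scaling = scaling,
                       features = feats),
                  class = "feature_matrix")
  list(fm = fm, truth = d$truth)
}

expect_one_warning <- function(expr, pattern) {
  expect_warning(expr, pattern)
}
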