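# Shared fixture builders; all randomness is seeded by the caller.

equal_design <- function(n) survey_design(rep(1, n))

## Two-stratum margin table on a single binary variable.
binary_margins <- function(var = "z", target1 = 0.5) {
  data.frame(variable = var, level = c("0", "1"),
             target = c(1 - target1, target1))
}

## Small p = 2 Ising truth with interaction log(2).
pair_truth <- function(edge = log(2), tau = c(0, 0)) {
  ising_truth(tau, matrix(c(0, edge, edge, 0), 2),
              labels = c("a", "b"))
}

## Raw survey table exercising every encoding rule.
raw_battery_fixture <- function() {
  singles <- setdiff(coendorse:::item_labels(), "likely_contact_u14")
  raw <- data.frame(matrix("no", 4, length(singles)),
                    stringsAsFactors = FALSE)
  names(raw) <- singles
  raw$viewed_csam <- c("yes", "no", "unsure", "maybe")
  raw$feelings <- c("no", "yes", "no", "no")
  raw$likely_12_14 <- c("never", "maybe", "very likely", "never")
  raw$likely_10_12 <- c("never", "unlikely", "maybe", "definitely")
  raw$likely_u10 <- c("never", "never", "never", "maybe")
  raw
}
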