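# Published integer I^2 values and classifications for the 16 bundled
# studies, used by the replay tests.
expected_replay <- tibble::tribble(
  ~trial_id, ~design,  ~i2_combined, ~result,
  "REF9",    "rct",    0L,           0L,
  "REF10",   "rct",    0L,           0L,
  "REF11",   "rct",    0L,           0L,
  "REF12",   "rct",    0L,           0L,
  "REF13",   "rct",    0L,           0L,
  "REF14",   "rct",    0L,           0L,
  "REF15",   "rct",    0L,           0L,
  "REF16",   "rct",    0L,           0L,
  "REF17",   "cohort", 71L,          1L,
  "REF18",   "cohort", 44L,          1L,
  "REF19",   "cohort", 17L,          1L,
  "REF20",   "cohort", 30L,          1L,
  "REF21",   "cohort", 37L,          1L,
  "REF22",   "cohort", 0L,           0L,
  "REF23",   "cohort", 86L,          1L,
  "REF24",   "cohort", 0L,           0L
)

# Independent direct-summation oracle for fixed-effect pooling: plain loops,
# no shared code with the package implementation.
oracle_pool <- function(md, variance) {
  k <- length(md)
  sw <- 0
  swm <- 0
  for (i in seq_len(k)) {
    sw <- sw + 1 / variance[i]
    swm <- swm + md[i] / variance[i]
  }
  pooled <- swm / sw
  q <- 0
  for (i in seq_len(k)) {
    q <- q + (md[i] - pooled)^2 / variance[i]
  }
  df <- k - 1
  i2 <- if (q <= df) 0 else 100 * (q - df) / q
  list(pooled_md = pooled, pooled_se = sqrt(1 / sw), q = q, df = df,
       i_squared = i2)
}
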