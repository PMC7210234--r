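# Shared fixture builders; everything is generated in code at test time.

make_lots <- function(test_values, ref_values, attribute = "attr",
                      unit = "%") {
  lot_table(data.frame(
    product = c(rep("test", length(test_values)),
                rep("reference", length(ref_values))),
    lot_id = c(sprintf("T%02d", seq_along(test_values)),
               sprintf("R%02d", seq_along(ref_values))),
    attribute = attribute,
    value = c(test_values, ref_values),
    unit = unit,
    stringsAsFactors = FALSE
  ))
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# First-principles Welch/pooled TOST decision, independent of the package's
# implementation (shared by the oracle-equivalence suites).
oracle_tost_pass <- function(test, ref, k1, alpha, mode = "welch") {
  n1 <- length(test); n2 <- length(ref)
  v1 <- sum((test - mean(test))^2) / (n1 - 1)
  v2 <- sum((ref - mean(ref))^2) / (n2 - 1)
  if (mode == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  d <- mean(test) - mean(ref)
  margin <- k1 * sqrt(v2)
  lo <- d - qt(1 - alpha, df) * se
  hi <- d + qt(1 - alpha, df) * se
  (lo > -margin) && (hi < margin)
}

oracle_qr_pass <- function(test, ref, k2, pass_fraction) {
  m <- mean(ref)
  s <- sqrt(sum((ref - mean(ref))^2) / (length(ref) - 1))
  inside <- sum(test >= m - k2 * s & test <= m + k2 * s)
  inside / length(test) >= pass_fraction
}
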