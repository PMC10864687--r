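# Round half away from zero at `digits` decimal places (display convention for
# report tables; internal computation is never rounded).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Format a proportion as a percent string at 1 d.p., half-up.
fmt_pct <- function(p, digits = 1) {
  ifelse(is.na(p), "-", paste0(format(round_half_up(100 * p, digits), nsmall = digits, trim = TRUE), "%"))
}

fmt_est_ci <- function(est, lo, hi, pct = TRUE, digits = if (pct) 1 else 3) {
  f <- function(x) {
    if (pct) format(round_half_up(100 * x, digits), nsmall = digits, trim = TRUE)
    else format(round_half_up(x, digits), nsmall = digits, trim = TRUE)
  }
  out <- ifelse(
    is.na(est), "-",
    ifelse(is.na(lo) | is.na(hi),
      paste0(f(est), if (pct) "%" else ""),
      paste0(f(est), if (pct) "%" else "", " (", f(lo), if (pct) "%" else "", "-",
             f(hi), if (pct) "%" else "", ")")
    )
  )
  out
}

# Minimal pipe-table emitter for the report writers; avoids a knitr dependency.
md_table <- function(df) {
  stopifnot(is.data.frame(df))
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, body)
}

match_variant <- function(variant) {
  rlang::arg_match0(variant, analysis_variants)
}
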