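# Shared fixtures, all built in code.

# Write a small UCI-dialect CSV and return its path.
write_toy_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# A 5-factor, 4-target toy table: 5 rows, one with a "?" in a retained factor.
toy_table_lines <- function() {
  c("f1,f2,f3,f4,f5,Hinselmann,Schiller,Cytology,Biopsy",
    "20,1,0,2.5,0,0,0,0,0",
    "30,0,1,?,1,0,1,0,1",
    "25,1,0,1.0,0,1,0,0,0",
    "40,0,0,3.5,1,0,0,1,0",
    "35,1,1,0.0,0,0,1,1,1")
}

# Small balanced 2-D separable data for MLP unit tests.
toy_separable_2d <- function(n = 60, seed = 1) {
  make_separable(n, n_factors = 2L, margin = 6, seed = seed)
}

# Independent brute-force metric arithmetic (oracle for compute_metrics).
oracle_metrics <- function(tn, fp, fn, tp) {
  div <- function(num, den) if (den == 0) 0 else num / den * 100
  sens <- div(tp, tp + fn)
  prec <- div(tp, tp + fp)
  list(accuracy = (tp + tn) / (tn + fp + fn + tp) * 100,
       sensitivity = sens,
       specificity = div(tn, tn + fp),
       precision = prec,
       f1 = if (sens + prec == 0) 0 else 2 * sens * prec / (sens + prec))
}
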