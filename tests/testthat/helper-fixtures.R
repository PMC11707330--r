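# Shared fixture builders. All synthetic inputs are generated in code.

# Fraction triple without going through integration.
frac <- function(f_lin, f_sc, f_oc) {
  structure(list(f_lin = f_lin, f_sc = f_sc, f_oc = f_oc),
            class = "isoform_fractions")
}

# A trace with an analytic signal on a regular grid.
fun_trace <- function(f, from = 0, to = 1000, by = 1, lane_id = "L1",
                      role = "sample", meta = list()) {
  tt <- seq(from, to, by = by)
  cge_trace(lane_id, tt, f(tt), role = role, meta = meta)
}

gauss <- function(t, center, sigma, area) area * dnorm(t, center, sigma)

# Write a wide trace CSV, returning its path.
write_trace_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

fractions_vec <- function(fr) c(fr$f_lin, fr$f_sc, fr$f_oc)

# Replicate summaries from a quant table grouped by prepared SC level.
level_summaries <- function(quant) replicate_summaries(quant)
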