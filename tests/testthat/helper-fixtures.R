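# Shared fixtures and helpers, all built in code.

# Reference polymer/solvent: 17.5 kDa PLA in THF.
pla_fixture <- function() {
  polymer_spec(
    molecular_weight = 17500, mh_K = 0.0174, mh_exponent = 0.736,
    kuhn_length = 8.81, kuhn_segments = 121, density = 1.25
  )
}

thf_fixture <- function() solvent_spec("THF", viscosity = 0.46)

# Measured batch-mean sizes for the reference PLA system: 4 core
# concentrations x 3 delay times (mirrors inst/extdata/pla_mp_sizes.csv).
size_records_fixture <- function() {
  tibble::tibble(
    c_core = rep(c(40, 60, 80, 100), each = 3),
    delay_time = rep(c(30, 60, 90), times = 4),
    diameter = c(1.59, 1.86, 2.24, 1.92, 2.24, 2.57,
                 2.01, 2.36, 2.87, 2.86, 2.88, 2.98),
    pdi = c(0.28, 0.12, 0.15, 0.11, 0.17, 0.12,
            0.29, 0.27, 0.34, 0.17, 0.24, 0.39),
    sd = c(0.01, 0.07, 0.05, 0.09, 0.09, 0.15,
           0.20, 0.17, 0.12, 0.11, 0.33, 0.35)
  )
}

# Greedy match of detections to ground-truth circles; returns per-truth
# relative radius error (NA where unmatched). A truth circle is matched if
# the nearest detection center lies within half its radius.
match_detections <- function(detections, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    d2 <- (detections$center_x - truth$center_x[i])^2 +
      (detections$center_y - truth$center_y[i])^2
    if (nrow(detections) == 0) return(NA_real_)
    j <- which.min(d2)
    if (sqrt(d2[j]) <= 0.5 * truth$radius[i]) {
      abs(detections$radius[j] - truth$radius[i]) / truth$radius[i]
    } else {
      NA_real_
    }
  }, numeric(1))
}
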