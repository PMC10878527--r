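#' @useDynLib vegfrtraffic, .registration = TRUE
NULL

# Shared constants; this file must collate before every other source file.

RECEPTORS <- c("R1", "R2", "N1")

TRAFFIC_PROCESSES <- c("k_int", "k_rec4", "k_4to11", "k_rec11", "k_deg")

LIVE_COMPARTMENTS <- c("SURFACE", "RAB4", "RAB11")

COUPLING_PAIRS <- c("R1R1", "R2R2", "R1N1")

# Bounds applied to every fitted first-order rate constant, in s^-1.
TRAFFIC_BOUNDS <- c(lower = 1e-6, upper = 1e-1)
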