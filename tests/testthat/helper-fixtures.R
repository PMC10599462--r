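# Shared fixtures built in code.

# reference truth used across mechanism tests: rapid equilibrium ordered with
# the nucleotide leading, constants on the scale of the SLA dehydrogenase assay
reo_truth <- function() kinetic_params(V = 17.8, Kia = 0.081, Kb = 0.13)

reo_model <- function() mechanism_model("RAPID_EQ_ORDERED", "NAD+")

# exact (noise-free) dataset on the reference grid
exact_reo_dataset <- function(replicates = 2) {
  generate_initial_rates(reo_model(), reo_truth(),
                         reference_bisubstrate_design(replicates))
}

# a dataset generated under an arbitrary mechanism with B leading: evaluate
# the rate law with swapped arguments so the E.B complex forms first
swapped_dataset <- function(model_name, p, design = reference_bisubstrate_design()) {
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      B = design$b_levels, A = design$a_levels)
  v <- rate_law(mechanism_model(model_name), grid$B, grid$A, p)
  rate_dataset(grid$A, grid$B, v, grid$replicate,
               a_label = design$a_label, b_label = design$b_label)
}

# random positive parameter draw for property-style loops
draw_params <- function() {
  list(V = stats::runif(1, 1, 50),
       Ka = stats::runif(1, 0.02, 0.3),
       Kb = stats::runif(1, 0.02, 0.3),
       Kia = stats::runif(1, 0.02, 0.3),
       alpha = stats::runif(1, 0.5, 3))
}

params_for <- function(model_name, q) {
  switch(model_name,
    PING_PONG = kinetic_params(V = q$V, Ka = q$Ka, Kb = q$Kb),
    ORDERED_STEADY_STATE = kinetic_params(V = q$V, Ka = q$Ka, Kb = q$Kb,
                                          Kia = q$Kia),
    RAPID_EQ_ORDERED = kinetic_params(V = q$V, Kb = q$Kb, Kia = q$Kia),
    RAPID_EQ_RANDOM = kinetic_params(V = q$V, Ka = q$Ka, Kb = q$Kb,
                                     alpha = q$alpha))
}

BIBI_MODELS <- c("PING_PONG", "ORDERED_STEADY_STATE", "RAPID_EQ_ORDERED",
                 "RAPID_EQ_RANDOM")
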