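# Builders for tiny in-code state tables and independent naive oracles used
# across the suite. The oracles evaluate the partition functions by direct
# summation (no log-sum-exp shift), valid for small energies only.

state_row <- function(molecule_id = "M1", tautomer_id = "M1_t1",
                      conformer_id = "c1", phase = "water",
                      E_sol = NA_real_, E_vac = NA_real_,
                      mu_ex = NA_real_, V_m = NA_real_, q = 0) {
  tibble::tibble(molecule_id = molecule_id, tautomer_id = tautomer_id,
                 conformer_id = conformer_id, phase = phase,
                 E_sol = E_sol, E_vac = E_vac, mu_ex = mu_ex, V_m = V_m, q = q)
}

sol_row <- function(..., E_sol = -500, mu_ex = -12, V_m = 180) {
  state_row(..., E_sol = E_sol, mu_ex = mu_ex, V_m = V_m)
}

vac_row <- function(molecule_id = "M1", tautomer_id = "M1_t1",
                    conformer_id = "v1", E_vac = -480, q = 0) {
  state_row(molecule_id, tautomer_id, conformer_id, phase = "vacuum",
            E_vac = E_vac, q = q)
}

# random valid state table over both partitioning phases plus vacuum;
# keep e_range small when comparing against the naive (unshifted) oracles
random_state_table <- function(n_molecules = 4, seed = 1,
                               e_range = c(-2000, -100)) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_molecules)) {
      mol <- sprintf("R%02d", i)
      for (phase in c("water", "octanol_wet")) {
        for (t in seq_len(sample(1:2, 1))) {
          for (c in seq_len(sample(1:3, 1))) {
            rows[[length(rows) + 1]] <- sol_row(
              mol, sprintf("%s_t%d", mol, t), sprintf("c%d", c), phase,
              E_sol = runif(1, e_range[1], e_range[2]),
              mu_ex = runif(1, -40, 5),
              V_m = runif(1, 50, 400))
          }
        }
      }
      rows[[length(rows) + 1]] <- vac_row(mol, sprintf("%s_t1", mol),
                                          E_vac = runif(1, e_range[1], e_range[2]))
    }
    dplyr::bind_rows(rows)
  })
}

# --- naive oracles (direct summation, small energies only) ------------------

naive_aggregate <- function(g, rt) -rt * log(sum(exp(-g / rt)))

# Eq.-by-eq composition: conformers within tautomer, then tautomers.
naive_molecule_G <- function(states, params, rt) {
  g_state <- states$E_sol + params$c_mu * states$mu_ex +
    params$c_V * states$V_m + params$c_q * states$q
  g_t <- tapply(g_state, states$tautomer_id, naive_aggregate, rt = rt)
  naive_aggregate(as.numeric(g_t), rt)
}

naive_training_loss <- function(states, experiments, params, solvent, rt) {
  sol <- states[states$phase == solvent, ]
  vac <- states[states$phase == "vacuum", ]
  exps <- experiments[experiments$observable == "dGsolv" &
                        experiments$solvent == solvent, ]
  total <- 0
  for (mol in unique(sol$molecule_id)) {
    s <- sol[sol$molecule_id == mol, ]
    u <- s$E_sol + params$c_mu * s$mu_ex + params$c_V * s$V_m + params$c_q * s$q
    g_sol <- naive_aggregate(u, rt) # pooled over all tautomer/conformer states
    g_vac <- naive_aggregate(vac$E_vac[vac$molecule_id == mol], rt)
    total <- total + (g_sol - g_vac - exps$value[exps$molecule_id == mol])^2
  }
  total
}
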