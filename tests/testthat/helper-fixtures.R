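# Small in-code fixtures shared across test files.

toy_quant <- function() {
  # one planted ablation, one 3-fold reduction, one unchanged
  quant_table(
    ids = c("gone", "down", "same"),
    mw_kda = c(10, 20, 30),
    values = list(
      WT = rbind(c(9, 10, 11), c(30, 30, 30), c(50, 50, 50)),
      KO = rbind(c(0, 0, 0), c(10, 10, 10), c(50, 50, 50))
    )
  )
}

# pipeline config over a simulate_screen_world() result
world_config <- function(w, outdir = NULL, seed = 1L) {
  list(quant = w$quant, wt_condition = "WT", ko_condition = "KO",
       criteria = w$criteria, annotations = w$annotations,
       homologs = w$homologs, proteome = w$proteome,
       signature = w$signature, min_len = w$length_window[1],
       max_len = w$length_window[2], direction = "both",
       outdir = outdir, seed = seed, workflow = "tether-screen")
}

ref_stoich_input <- function() {
  ref <- doublet_stoich_ref()
  data.frame(protein_id = ref$protein_id, mw_kda = ref$mw_kda,
             aqv = ref$aqv, stringsAsFactors = FALSE)
}
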