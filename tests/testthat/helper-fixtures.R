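# Printed study inputs used across tests: the two designed peptides and the
# per-species MIC panel (micromolar).

le_peptides <- tibble::tibble(
  id = c("LE-53", "LE-55"),
  sequence = c("RRRRRRWWWWVV", "RRRRRRRRWWWWVVVV"))

mic_panel_gneg <- tibble::tibble(
  peptide = rep(c("LE-53", "LE-55", "colistin", "tobramycin"), each = 5),
  species = rep(c("PA", "AB", "KP", "EC", "Entbac"), times = 4),
  group = "G-",
  mic = c(10.7, 3.3, 3.6, 4.8, 6.5,
          32.0, 21.3, 32.0, 28.8, 32.0,
          8.4, 0.5, 0.7, 4.3, 12.1,
          32.0, 32.0, 2.1, 28.0, 24.5))

mic_panel_gpos <- tibble::tibble(
  peptide = rep(c("LE-53", "LE-55"), each = 2),
  species = rep(c("Entcoc", "SA"), times = 2),
  group = "G+",
  mic = c(14.4, 2.0, 28.0, 24.0))

# small smectic stack used by the elasticity tests (desk-scale conditions)
test_stack <- function(K_C = 20, B = 2e-6, N = 16, L_r = 800, D = 60) {
  stack_model(K_C = K_C, B = B, N_layers = N, L_r = L_r, D = D)
}
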