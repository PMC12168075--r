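# Shared fixtures and independent oracles for the tests.

fixtures <- rna_studied()
SEQ18 <- fixtures$sequence[fixtures$id == 1]
SEQ27 <- fixtures$sequence[fixtures$id == 6]
SEQ8 <- fixtures$sequence[fixtures$id == 10]

# independent mass oracle: atomic masses and nucleoside formulas restated
# here by hand, no package code involved
oracle_atomic <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151)
oracle_mass <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  sum(c(C, H, N, O, P) * oracle_atomic)
}
oracle_nucleoside <- list(
  A = c(10, 13, 5, 4, 0), C = c(9, 13, 3, 5, 0), G = c(10, 13, 5, 5, 0),
  U = c(9, 12, 2, 6, 0)
)
oracle_seq_mass <- function(tokens) {
  cc <- Reduce(`+`, oracle_nucleoside[tokens])
  linkage <- c(0, -1, 0, 2, 1) # HPO3 - H2O
  cc <- cc + (length(tokens) - 1) * linkage
  do.call(oracle_mass, as.list(cc))
}

# yields computed straight from simulator ground truth, bypassing peak
# rendering/matching: abundance = ion count x charge, as rendered
truth_assignments <- function(sim) {
  sp <- sim$truth$species_visible
  tibble::tibble(
    ion_type = sp$ion_type, index = sp$index, base_loss = sp$base_loss,
    charge = sp$charge, abundance = sp$count * sp$charge,
    ambiguous = FALSE
  )
}

# species identity key: base-loss positions map onto the lost-base mass,
# since losing the same base from different positions is one observable
species_key <- function(d, seq) {
  seq <- parse_rna(seq)
  rt <- residue_table()
  bm <- rt$base_mass[match(seq$residues[d$base_loss], rt$code)]
  paste(d$ion_type, d$index, d$charge,
        round(ifelse(is.na(d$base_loss), 0, bm), 3))
}

cy_candidates <- function(seq, n, base_loss = TRUE) {
  enumerate_fragments(seq, c("c", "y", "precursor"), max_charge = n,
                      base_loss = base_loss)
}
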