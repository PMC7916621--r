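# Small fixture networks built in code.

toy_constant_chain <- function() {
  # A constant, B follows A, C negates B
  boolean_network(c(A = "1", B = "A", C = "!B"))
}

toy_oscillator <- function() {
  # 2-node negative feedback loop: period-4 cycle through all 4 states
  boolean_network(c(A = "!B", B = "A"))
}

toy_identity <- function() {
  boolean_network(c(A = "A"))
}

toy_negation <- function() {
  boolean_network(c(A = "!A"))
}

delayed_pair <- function() {
  # B reads A two steps back: one register A.d1
  boolean_network(c(A = "!A", B = "A(-2)"))
}

cancer_attractor_active <- c(
  "CFL1", "TCF7L2", "AURKA", "SSH1L", "RAC1", "ARP2/3", "F-actin_new",
  "F-actin_old", "STAT3", "AKT", "CTNNB1", "MYC", "CCND1", "E2F", "CCNE1",
  "S-phase", "CD44", "TWIST1", "PAK1", "PAK4", "PI3K", "KRAS",
  "Phosphorylated-CFL1", "Anti-apoptotic proteins")

cancer_attractor_inactive <- c(
  "PRKD1", "RHOA", "LIMK", "GSK3B", "RB", "CDH1", "Pro-apoptotic proteins",
  "CYCS", "Caspases")

# keys of an attractor set, sorted
aset_keys <- function(aset) sort(names(aset$attractors))
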