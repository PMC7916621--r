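# Logical model of cofilin-1 (CFL1) signalling in pancreatic ductal adenocarcinoma.
# 33 nodes; KRAS constitutively active; delays (-k) abstract linear cascades.
targets, factors
TCF7L2, !PRKD1
AURKA, PAK1
Phosphorylated-CFL1, CD44 | TCF7L2 | (CFL1 & LIMK & !SSH1L)
CFL1, (SSH1L & Phosphorylated-CFL1) | (SSH1L & LIMK & Phosphorylated-CFL1)
CD44, TWIST1
TWIST1, AURKA
LIMK, (RHOA | PAK1 | PAK4) & !SSH1L
SSH1L, ((F-actin_new | F-actin_old) & !PRKD1) | (PI3K & AURKA) | (LIMK & SSH1L)
F-actin_new, (CFL1 & ARP2/3) | (RHOA(-3) & !CFL1)
F-actin_old, (F-actin_old & !CFL1) | F-actin_new
ARP2/3, RAC1(-2)
KRAS, 1
PI3K, KRAS | CD44
PRKD1, RHOA
RHOA, !PAK4
RAC1, PI3K | Phosphorylated-CFL1(-3)
PAK1, RAC1
PAK4, RAC1
CDH1, !TWIST1
CTNNB1, PAK1 & !PRKD1 & !CDH1
GSK3B, !AKT
MYC, (!GSK3B & STAT3) | (CTNNB1 & !GSK3B)
CCND1, !GSK3B & MYC & AKT
RB, !CCND1
E2F, !RB
CCNE1, E2F
S-phase, E2F & CCNE1
AKT, PI3K & STAT3
STAT3, (Phosphorylated-CFL1 | CFL1) & CD44
"Anti-apoptotic proteins", STAT3
"Pro-apoptotic proteins", !AKT
CYCS, "Pro-apoptotic proteins" & !"Anti-apoptotic proteins" & CFL1
Caspases, CYCS & !AKT
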