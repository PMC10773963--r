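# Model library: the four cell-cycle transition switches and the merged
# oscillating core model.  All reactions are mass action; concentrations
# are in arbitrary units, time in minutes.  Only kDipEB55 = 0.0068 and
# kAspEB55 = 57 (ENSA/B55 association kinetics measured by Williams et
# al.) are literature-fixed; the remaining constants were chosen so that
# each switch is bistable, the merged model oscillates stably, and
# restriction-point / knockout behaviour matches what is observed in
# cells (see the methods vignette).

rx <- function(...) reaction(...)  # local shorthand

# ---- default rate constants ------------------------------------------------

default_rates <- function() c(
  ## Rb/E2F restriction point
  kPhRbD   = 0.80,   # Rb phosphorylation by CycD (per AU_D per min)
  kPhRbE   = 0.50,   # Rb phosphorylation by CycE
  kPhRb    = 0.01,   # basal Rb phosphorylation
  kDpRb    = 0.25,   # Rb dephosphorylation
  kAsRE    = 25,     # Rb + E2f association
  kDiRE    = 0.02,   # Rb:E2f dissociation
  kSyE2f   = 0.0010, # basal E2f synthesis
  kSyE2fA  = 0.0285,  # E2f autoactivation (transcription driven by free E2f)
  kDeE2f   = 0.03,   # E2f degradation (free)
  kDeE2fC  = 0.002,  # E2f turnover inside the Rb:E2f complex (protected)
  kSyCe    = 0.10,   # CycE synthesis (E2f-driven)
  kDeCe    = 0.02,   # basal CycE degradation
  kDeCeA   = 1.20,   # CycE phosphorylation by CycA -> immediate degradation
  ## G1/S: CycA vs Apc:Cdh1 with Emi1
  kSyCa    = 0.060,  # CycA synthesis (E2f-driven)
  kDeCa    = 0.02,   # basal CycA degradation
  kDeCaC   = 3.0,    # CycA degradation by Apc:Cdh
  kDeCaC20 = 5.00,   # CycA degradation by pApc:Cdc20
  kPhCdhA  = 10,    # Cdh phosphorylation by CycA
  kPhCdhE  = 0.5,    # Cdh phosphorylation by CycE
  kPhCdhB  = 10,    # Cdh phosphorylation by CycB:Cdk1
  kDpCdh   = 0.25,   # basal Cdh dephosphorylation
  kDpCdhB55= 3.0,     # Cdh dephosphorylation by B55
  kAsACE   = 20,     # Apc:Cdh + Emi1 association
  kDiACE   = 0.05,   # Apc:Cdh:Emi1 dissociation
  kDeEmiC  = 0.03,   # slow Emi1 turnover inside the complex
  kSyEmi   = 0.070,  # Emi1 synthesis (E2f-driven)
  kDeEmi   = 0.002,   # basal Emi1 degradation
  kDeEmiB  = 1.0,    # mitotic Emi1 degradation (CycB:Cdk1-marked)
  ## G2/M: Wee1/Cdc25 + Gw/ENSA/B55 single switch
  kWee     = 10,     # Cdk1 Tyr15 phosphorylation by Wee1
  kWee0    = 0.10,   # basal Cdk1 phosphorylation
  kC25     = 10,     # Cdk1 dephosphorylation by active Cdc25
  kC250    = 0.05,   # basal Cdk1 dephosphorylation
  kPhWee   = 10,     # Wee1 inactivation by CycB:Cdk1
  kDpWeeB55= 20,     # Wee1 reactivation by B55
  kDpWee   = 0.20,   # basal Wee1 reactivation
  kPhC25   = 10,     # Cdc25 activation by CycB:Cdk1
  kDpC25B55= 20,     # Cdc25 inactivation by B55
  kDpC25   = 0.20,   # basal Cdc25 inactivation
  kPhGw    = 10,     # Greatwall activation by CycB:Cdk1
  kDpGwB55 = 25,     # Greatwall inactivation by B55
  kDpGw    = 1.00,   # basal Greatwall inactivation
  kPhEnsa  = 8,     # Ensa phosphorylation by pGw
  kAspEB55 = 57,     # pEnsa + B55 association (Williams et al.)
  kDipEB55 = 0.0068, # pEnsa:B55 dissociation (Williams et al.)
  kDpEnsa  = 0.40,   # catalytic dephosphorylation of bound pEnsa
  ## M/A: Apc/Cdc20 negative feedback and cyclin B turnover
  kPhApc   = 0.50,    # Apc phosphorylation by CycB:Cdk1
  kDpApcB55= 6.00,    # Apc dephosphorylation by B55
  kDpApc   = 0.01,   # basal Apc dephosphorylation
  kAsApcC20= 2.0,     # pApc + Cdc20 association
  kDiApcC20= 0.05,   # pApc:Cdc20 dissociation
  kSyCb    = 0.04,   # basal cyclin B synthesis (MA submodel bifurcation param)
  kSyCbA   = 0.04,   # CycA-driven cyclin B synthesis (core model)
  kDeCb    = 0.001,  # basal cyclin B degradation
  kDeCbC   = 0.25,   # cyclin B degradation by Apc:Cdh
  kDeCbC20 = 8.00    # cyclin B degradation by pApc:Cdc20
)

default_checkpoint_rates <- function() c(
  kSyP21   = 0.12,   # CDKN1A synthesis, TP53-driven
  kDeP21   = 0.01,   # basal CDKN1A degradation
  kDeP21S  = 2.0,    # SKP2/SCF-marked CDKN1A degradation
  kSySkp2  = 0.02,   # SKP2 synthesis
  kDeSkp2  = 0.02,   # basal SKP2 degradation
  kDeSkp2C = 1.0,    # SKP2 degradation by Apc:Cdh (G1)
  kAsP21   = 50,     # CDKN1A + cyclin association
  kDiP21   = 0.05,   # cyclin:CDKN1A dissociation
  kDeCyP21 = 0.05    # cyclin turnover inside CDKN1A complexes
)

default_cdkn1b_rates <- function() c(
  kSyP27   = 0.004,  # CDKN1B synthesis (TP53-independent)
  kDeP27   = 0.008,  # basal CDKN1B degradation
  kDeP27S  = 1.0,    # SKP2-marked CDKN1B degradation
  kAsP27   = 50,     # CDKN1B + cyclin association
  kDiP27   = 0.05,   # cyclin:CDKN1B dissociation
  kDeCyP27 = 0.05    # cyclin turnover inside CDKN1B complexes
)

# ---- reaction blocks -------------------------------------------------------

# Rb/E2F toggle.  `autoactivation`: transcriptional E2f autoactivation;
# when FALSE, total E2f is a conserved pool (no synthesis/turnover).
rp_block <- function(autoactivation = TRUE) {
  r <- list(
    rx("PhRbD",  "kPhRbD", c(Rb = 1),    "CycD", c(pRb = 1)),
    rx("PhRbE",  "kPhRbE", c(Rb = 1),    "CycE", c(pRb = 1)),
    rx("PhRb",   "kPhRb",  c(Rb = 1),    character(0), c(pRb = 1)),
    rx("DpRb",   "kDpRb",  c(pRb = 1),   character(0), c(Rb = 1)),
    rx("PhRbDc", "kPhRbD", c(RbE2f = 1), "CycD", c(pRb = 1, E2f = 1)),
    rx("PhRbEc", "kPhRbE", c(RbE2f = 1), "CycE", c(pRb = 1, E2f = 1)),
    rx("PhRbc",  "kPhRb",  c(RbE2f = 1), character(0), c(pRb = 1, E2f = 1)),
    rx("AsRE",   "kAsRE",  c(Rb = 1, E2f = 1), character(0), c(RbE2f = 1)),
    rx("DiRE",   "kDiRE",  c(RbE2f = 1), character(0), c(Rb = 1, E2f = 1))
  )
  if (autoactivation) {
    r <- c(r, list(
      rx("SyE2f",  "kSyE2f",  numeric(0), character(0), c(E2f = 1)),
      rx("SyE2fA", "kSyE2fA", numeric(0), "E2f", c(E2f = 1)),
      rx("DeE2f",  "kDeE2f",  c(E2f = 1), character(0), numeric(0)),
      rx("DeE2fC", "kDeE2fC", c(RbE2f = 1), character(0), c(Rb = 1))
    ))
  }
  r
}

g1s_block <- function() list(
  rx("SyCa",   "kSyCa",   numeric(0),   "E2f",  c(CycA = 1)),
  rx("DeCa",   "kDeCa",   c(CycA = 1),  character(0), numeric(0)),
  rx("DeCaC",  "kDeCaC",  c(CycA = 1),  "Cdh",  numeric(0)),
  rx("PhCdhA", "kPhCdhA", c(Cdh = 1),   "CycA", c(pCdh = 1)),
  rx("PhCdhE", "kPhCdhE", c(Cdh = 1),   "CycE", c(pCdh = 1)),
  rx("DpCdh",  "kDpCdh",  c(pCdh = 1),  character(0), c(Cdh = 1)),
  rx("PhCdhAc","kPhCdhA", c(CdhEmi = 1), "CycA", c(pCdh = 1, Emi1 = 1)),
  rx("PhCdhEc","kPhCdhE", c(CdhEmi = 1), "CycE", c(pCdh = 1, Emi1 = 1)),
  rx("AsACE",  "kAsACE",  c(Cdh = 1, Emi1 = 1), character(0), c(CdhEmi = 1)),
  rx("DiACE",  "kDiACE",  c(CdhEmi = 1), character(0), c(Cdh = 1, Emi1 = 1)),
  rx("DeEmiC", "kDeEmiC", c(CdhEmi = 1), character(0), c(Cdh = 1)),
  rx("SyEmi",  "kSyEmi",  numeric(0),   "E2f",  c(Emi1 = 1)),
  rx("DeEmi",  "kDeEmi",  c(Emi1 = 1),  character(0), numeric(0))
)

g2m_block <- function() list(
  rx("PhCb",   "kWee",     c(Cb = 1),     "Wee1",   c(pCb = 1)),
  rx("PhCb0",  "kWee0",    c(Cb = 1),     character(0), c(pCb = 1)),
  rx("DpCb",   "kC25",     c(pCb = 1),    "pCdc25", c(Cb = 1)),
  rx("DpCb0",  "kC250",    c(pCb = 1),    character(0), c(Cb = 1)),
  rx("PhWee",  "kPhWee",   c(Wee1 = 1),   "Cb",  c(pWee1 = 1)),
  rx("DpWeeB", "kDpWeeB55",c(pWee1 = 1),  "B55", c(Wee1 = 1)),
  rx("DpWee",  "kDpWee",   c(pWee1 = 1),  character(0), c(Wee1 = 1)),
  rx("PhC25",  "kPhC25",   c(Cdc25 = 1),  "Cb",  c(pCdc25 = 1)),
  rx("DpC25B", "kDpC25B55",c(pCdc25 = 1), "B55", c(Cdc25 = 1)),
  rx("DpC25",  "kDpC25",   c(pCdc25 = 1), character(0), c(Cdc25 = 1)),
  rx("PhGw",   "kPhGw",    c(Gw = 1),     "Cb",  c(pGw = 1)),
  rx("DpGwB",  "kDpGwB55", c(pGw = 1),    "B55", c(Gw = 1)),
  rx("DpGw",   "kDpGw",    c(pGw = 1),    character(0), c(Gw = 1)),
  rx("PhEnsa", "kPhEnsa",  c(Ensa = 1),   "pGw", c(pEnsa = 1)),
  rx("AspEB",  "kAspEB55", c(pEnsa = 1, B55 = 1), character(0), c(pEB55 = 1)),
  rx("DipEB",  "kDipEB55", c(pEB55 = 1),  character(0), c(pEnsa = 1, B55 = 1)),
  rx("DpEnsa", "kDpEnsa",  c(pEB55 = 1),  character(0), c(Ensa = 1, B55 = 1))
)

ma_block <- function() list(
  rx("PhApc",  "kPhApc",   c(Apc = 1),  "Cb",  c(pApc = 1)),
  rx("DpApcB", "kDpApcB55",c(pApc = 1), "B55", c(Apc = 1)),
  rx("DpApc",  "kDpApc",   c(pApc = 1), character(0), c(Apc = 1)),
  rx("AsApcC20","kAsApcC20",c(pApc = 1, Cdc20 = 1), character(0), c(ApcC20 = 1)),
  rx("DiApcC20","kDiApcC20",c(ApcC20 = 1), character(0), c(pApc = 1, Cdc20 = 1)),
  rx("DpApcC20B","kDpApcB55", c(ApcC20 = 1), "B55", c(Apc = 1, Cdc20 = 1)),
  rx("DeCbC20", "kDeCbC20", c(Cb = 1),  "ApcC20", numeric(0)),
  rx("DepCbC20","kDeCbC20", c(pCb = 1), "ApcC20", numeric(0)),
  rx("DeCb",    "kDeCb",    c(Cb = 1),  character(0), numeric(0)),
  rx("DepCb",   "kDeCb",    c(pCb = 1), character(0), numeric(0))
)

checkpoint_block <- function() list(
  rx("SyP21",  "kSyP21",  numeric(0),    "TP53", c(P21 = 1)),
  rx("DeP21",  "kDeP21",  c(P21 = 1),    character(0), numeric(0)),
  rx("DeP21S", "kDeP21S", c(P21 = 1),    "SKP2", numeric(0)),
  rx("SySkp2", "kSySkp2", numeric(0),    character(0), c(SKP2 = 1)),
  rx("DeSkp2", "kDeSkp2", c(SKP2 = 1),   character(0), numeric(0)),
  rx("DeSkp2C","kDeSkp2C",c(SKP2 = 1),   "Cdh", numeric(0)),
  rx("AsCeP21","kAsP21",  c(CycE = 1, P21 = 1), character(0), c(CeP21 = 1)),
  rx("DiCeP21","kDiP21",  c(CeP21 = 1),  character(0), c(CycE = 1, P21 = 1)),
  rx("DeCeP21","kDeCyP21",c(CeP21 = 1),  character(0), c(P21 = 1)),
  rx("AsCaP21","kAsP21",  c(CycA = 1, P21 = 1), character(0), c(CaP21 = 1)),
  rx("DiCaP21","kDiP21",  c(CaP21 = 1),  character(0), c(CycA = 1, P21 = 1)),
  rx("DeCaP21","kDeCyP21",c(CaP21 = 1),  character(0), c(P21 = 1)),
  rx("AsCbP21","kAsP21",  c(Cb = 1, P21 = 1), character(0), c(CbP21 = 1)),
  rx("DiCbP21","kDiP21",  c(CbP21 = 1),  character(0), c(Cb = 1, P21 = 1)),
  rx("DeCbP21","kDeCyP21",c(CbP21 = 1),  character(0), c(P21 = 1))
)

cdkn1b_block <- function() list(
  rx("SyP27",  "kSyP27",  numeric(0),    character(0), c(P27 = 1)),
  rx("DeP27",  "kDeP27",  c(P27 = 1),    character(0), numeric(0)),
  rx("DeP27S", "kDeP27S", c(P27 = 1),    "SKP2", numeric(0)),
  rx("AsCeP27","kAsP27",  c(CycE = 1, P27 = 1), character(0), c(CeP27 = 1)),
  rx("DiCeP27","kDiP27",  c(CeP27 = 1),  character(0), c(CycE = 1, P27 = 1)),
  rx("DeCeP27","kDeCyP27",c(CeP27 = 1),  character(0), c(P27 = 1)),
  rx("AsCaP27","kAsP27",  c(CycA = 1, P27 = 1), character(0), c(CaP27 = 1)),
  rx("DiCaP27","kDiP27",  c(CaP27 = 1),  character(0), c(CycA = 1, P27 = 1)),
  rx("DeCaP27","kDeCyP27",c(CaP27 = 1),  character(0), c(P27 = 1))
)

# Default initial pools (conserved totals enter through these).
g2m_init <- function(tCycB = 0) c(
  Cb = 0, pCb = tCycB, Wee1 = 0.5, pWee1 = 0, Cdc25 = 0.5, pCdc25 = 0,
  Gw = 0.4, pGw = 0, Ensa = 0.5, pEnsa = 0, B55 = 0.25, pEB55 = 0)

ma_init <- function() c(Apc = 1, pApc = 0, ApcC20 = 0, Cdc20 = 0.5)

g2m_conserved <- function(with_cycb = TRUE) {
  g <- list(tWee1 = c("Wee1", "pWee1"), tCdc25 = c("Cdc25", "pCdc25"),
            tGw = c("Gw", "pGw"), tEnsa = c("Ensa", "pEnsa", "pEB55"),
            tB55 = c("B55", "pEB55"))
  if (with_cycb) g <- c(list(tCycB = c("Cb", "pCb")), g)
  g
}

# ---- public constructors ---------------------------------------------------

#' Build one of the four cell-cycle transition submodels
#'
#' * `"RP"` — restriction point: Rb/E2F toggle with CycD as clamped
#'   mitogen input; bistable in CycD.  `e2f_autoactivation = FALSE`
#'   freezes total E2f as a conserved pool of 0.5 AU, which narrows the
#'   bistable window.
#' * `"G1S"` — CycA versus Apc:Cdh1 toggle with Emi1 sequestration;
#'   clamped inputs E2f and CycE; total Cdh is conserved.
#' * `"G2M"` — Wee1/Cdc25 plus Greatwall/ENSA/B55 single bistable switch;
#'   the bifurcation input is the conserved total cyclin B (set through
#'   the initial conditions of `Cb`/`pCb`).
#' * `"MA"` — the G2/M switch extended by Apc/Cdc20-mediated cyclin B
#'   degradation and constant-rate synthesis `kSyCb`; oscillates above a
#'   critical `kSyCb` (Hopf bifurcation).
#'
#' @param name submodel name
#' @param e2f_autoactivation include transcriptional E2f autoactivation
#'   (RP submodel only)
#' @return a `ccModel`
#' @export
build_submodel <- function(name = c("RP", "G1S", "G2M", "MA"),
                           e2f_autoactivation = TRUE) {
  name <- match.arg(name)
  k <- default_rates()
  if (name == "RP") {
    species <- c("Rb", "pRb", "RbE2f", "E2f", "CycE", "CycD")
    reactions <- c(rp_block(e2f_autoactivation), list(
      rx("SyCe", "kSyCe", numeric(0), "E2f", c(CycE = 1)),
      rx("DeCe", "kDeCe", c(CycE = 1), character(0), numeric(0))))
    init <- c(Rb = 1.2, pRb = 0, RbE2f = 0, E2f = 0, CycE = 0, CycD = 0)
    conserved <- list(tRb = c("Rb", "pRb", "RbE2f"))
    if (!e2f_autoactivation) {
      init["E2f"] <- 0.5   # conserved total E2f pool of 0.5 AU
      conserved$tE2f <- c("E2f", "RbE2f")
    }
    m <- reaction_model("rp", species, reactions, k, init, conserved,
                        clamped = "CycD")
  } else if (name == "G1S") {
    species <- c("CycA", "Cdh", "pCdh", "CdhEmi", "Emi1", "E2f", "CycE")
    init <- c(CycA = 0, Cdh = 0.84, pCdh = 0.03, CdhEmi = 0, Emi1 = 0,
              E2f = 0, CycE = 0)
    m <- reaction_model("g1s", species, g1s_block(), k, init,
                        conserved = list(tCdh = c("Cdh", "pCdh", "CdhEmi")),
                        clamped = c("E2f", "CycE"))
  } else if (name == "G2M") {
    species <- names(g2m_init())
    m <- reaction_model("g2m", species, g2m_block(), k, g2m_init(0),
                        conserved = g2m_conserved(TRUE))
  } else {
    species <- c(names(g2m_init()), names(ma_init()))
    reactions <- c(g2m_block(), ma_block(), list(
      rx("SyCb", "kSyCb", numeric(0), character(0), c(Cb = 1))))
    init <- c(g2m_init(0), ma_init())
    cons <- c(g2m_conserved(FALSE),
              list(tApc = c("Apc", "pApc", "ApcC20"),
                   tCdc20 = c("Cdc20", "ApcC20")))
    # standalone oscillator: basal turnover stands in for the Cdh/Cdc20-
    # independent cyclin B degradation routes of the full model, placing
    # the oscillation threshold at a biologically plausible synthesis rate
    k["kDeCb"] <- 0.12
    m <- reaction_model("ma", species, reactions, k, init, cons)
    m$ma_species <- c("Cb", "pCb")
  }
  m
}

#' Build the merged core cell-cycle model
#'
#' Fuses the four transition submodels into one oscillating network:
#' E2f (released by CycD/CycE-mediated Rb phosphorylation) drives CycE,
#' CycA and Emi1 synthesis; CycA flips the G1/S toggle, marks CycE for
#' degradation and drives cyclin B synthesis; the G2/M switch activates
#' CycB:Cdk1, which phosphorylates Apc; pApc:Cdc20 degrades cyclins A/B
#' and mitotic Emi1, letting B55 and Apc:Cdh reactivate for the next G1.
#' CycD is a clamped mitogen input (default 1 AU).
#'
#' With `checkpoint = TRUE` the DNA-damage machinery is added: clamped
#' TP53 drives CDKN1A (p21) synthesis, SKP2 marks it for degradation
#' (SKP2 itself is degraded by Apc:Cdh in G1), and CDKN1A binds CycE,
#' CycA and CycB:Cdk1 stoichiometrically.  `cdkn1b = TRUE` (requires the
#' checkpoint) adds CDKN1B (p27) as a second stoichiometric inhibitor.
#'
#' @param checkpoint add the TP53/CDKN1A/SKP2 DNA-damage checkpoint
#' @param cdkn1b add CDKN1B as a second stoichiometric cyclin inhibitor
#' @param compartments duplicate the model into nucleus and cytoplasm
#'   (symmetric transport with rate `transport_rate` for every species)
#' @param transport_rate default import/export rate constant (1/min)
#'   used when `compartments = TRUE`
#' @return a `ccModel` (M/A events annotated on total cyclin B)
#' @export
build_core_model <- function(checkpoint = FALSE, cdkn1b = FALSE,
                             compartments = FALSE, transport_rate = 0.1) {
  if (cdkn1b && !checkpoint)
    stop("cdkn1b = TRUE requires checkpoint = TRUE")
  k <- default_rates()
  species <- c("Rb", "pRb", "RbE2f", "E2f", "CycE", "CycD",
               "CycA", "Cdh", "pCdh", "CdhEmi", "Emi1",
               names(g2m_init()), names(ma_init()))
  reactions <- c(
    rp_block(TRUE),
    list(rx("SyCe",  "kSyCe",  numeric(0),  "E2f",  c(CycE = 1)),
         rx("DeCe",  "kDeCe",  c(CycE = 1), character(0), numeric(0)),
         rx("DeCeA", "kDeCeA", c(CycE = 1), "CycA", numeric(0))),
    g1s_block(),
    list(rx("DeCaC20", "kDeCaC20", c(CycA = 1), "ApcC20", numeric(0)),
         rx("PhCdhB",  "kPhCdhB",  c(Cdh = 1),  "Cb", c(pCdh = 1)),
         rx("PhCdhBc", "kPhCdhB",  c(CdhEmi = 1), "Cb", c(pCdh = 1, Emi1 = 1)),
         rx("DpCdhB",  "kDpCdhB55",c(pCdh = 1), "B55", c(Cdh = 1)),
         rx("DeEmiB",  "kDeEmiB",  c(Emi1 = 1), "Cb", numeric(0)),
         rx("DeEmiBc", "kDeEmiB",  c(CdhEmi = 1), "Cb", c(Cdh = 1)),
         rx("DeEmiC20","kDeEmiC20",c(Emi1 = 1), "ApcC20", numeric(0)),
         rx("DeEmiC20c","kDeEmiC20",c(CdhEmi = 1), "ApcC20", c(Cdh = 1))),
    g2m_block(),
    ma_block(),
    list(rx("SyC20",  "kSyC20",  numeric(0), "CycA", c(Cdc20 = 1)),
         rx("SyC20E", "kSyC20E", numeric(0), "E2f", c(Cdc20 = 1)),
         rx("DeC20",  "kDeC20",  c(Cdc20 = 1), character(0), numeric(0)),
         rx("DeC20C", "kDeC20C", c(Cdc20 = 1), "Cdh", numeric(0)),
         rx("DeC20x", "kDeC20",  c(ApcC20 = 1), character(0), c(pApc = 1)),
         rx("SyCbA", "kSyCbA", numeric(0), "CycA", c(Cb = 1)),
         rx("SyCbE", "kSyCbE", numeric(0), "E2f", c(Cb = 1)),
         rx("SyCb0", "kSyCb0", numeric(0), character(0), c(Cb = 1)),
         rx("DeCbC", "kDeCbC", c(Cb = 1),  "Cdh", numeric(0)),
         rx("DepCbC","kDeCbC", c(pCb = 1), "Cdh", numeric(0)))
  )
  k <- c(k, kSyCb0 = 0.001, kDeEmiC20 = 2.0, kSyC20 = 0.02,
         kDeC20 = 0.05, kDeC20C = 0.5, kSyCbE = 0.015, kSyC20E = 0.01)
  k["kSyCb"] <- 0   # constant-rate synthesis replaced by CycA-driven term
  # default initial conditions lie on the wild-type limit cycle, anchored
  # at an M/A transition (so simulations start at division, age 0)
  init <- c(Rb = 0.0243208, pRb = 0.941302, RbE2f = 0.234378,
            E2f = 0.359054, CycE = 0.207157, CycD = 1, CycA = 0.0796156,
            Cdh = 0.0437586, pCdh = 0.743531, CdhEmi = 0.0827105,
            Emi1 = 0.178631, Cb = 0.0497374, pCb = 0.0233598,
            Wee1 = 0.166701, pWee1 = 0.333299, Cdc25 = 0.166701,
            pCdc25 = 0.333299, Gw = 0.260624, pGw = 0.139376,
            Ensa = 0.0723396, pEnsa = 0.1868, B55 = 0.00913898,
            pEB55 = 0.240861, Apc = 0.683617, pApc = 0.252031,
            ApcC20 = 0.0643519, Cdc20 = 0.0253686)
  conserved <- c(list(tRb = c("Rb", "pRb", "RbE2f"),
                      tCdh = c("Cdh", "pCdh", "CdhEmi")),
                 g2m_conserved(FALSE),
                 list(tApc = c("Apc", "pApc", "ApcC20")))
  if (checkpoint) {
    species <- c(species, "TP53", "P21", "SKP2", "CeP21", "CaP21", "CbP21")
    reactions <- c(reactions, checkpoint_block())
    k <- c(k, default_checkpoint_rates())
    init <- c(init, TP53 = 0, P21 = 0, SKP2 = 0.5, CeP21 = 0, CaP21 = 0,
              CbP21 = 0)
  }
  if (cdkn1b) {
    species <- c(species, "P27", "CeP27", "CaP27")
    reactions <- c(reactions, cdkn1b_block())
    k <- c(k, default_cdkn1b_rates())
    init <- c(init, P27 = 0, CeP27 = 0, CaP27 = 0)
  }
  clamped <- c("CycD", if (checkpoint) "TP53")
  m <- reaction_model(if (checkpoint) "core_checkpoint" else "core",
                      species, reactions, k, init, conserved, clamped)
  m$ma_species <- c("Cb", "pCb")
  if (compartments) {
    tr <- setNames(rep(list(c(transport_rate, transport_rate)),
                       length(m$species)), m$species)
    tr[m$clamped] <- NULL
    m <- compartmentalise(m, tr)
  }
  m
}
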