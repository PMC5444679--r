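## The packaged 56-reaction central-metabolism reconstruction of
## Kluyveromyces marxianus: glycolysis/gluconeogenesis, pentose phosphate
## pathway, TCA cycle, glyoxylate shunt, fermentative branches (ethanol,
## glycerol, acetate, ethyl acetate), xylose assimilation, a four-reaction
## beta-oxidation block, lumped electron transport / oxidative
## phosphorylation, and a biomass drain.
##
## Conventions: single compartment, one pool per cofactor; protons are not
## tracked; water is tracked but freely exchangeable (its balance never
## constrains); orthophosphate is tracked with an always-open exchange.
## AMP-forming ligases are written as two ATP -> ADP equivalents (adenylate
## kinase folded in).  Electron transport is lumped at P/O 2.5 for NADH
## (vETC); succinate-derived electrons are lumped into the succinate
## dehydrogenase step at P/O 1.5.

.kmMetabolites <- function() {
    ## id, name, isCofactor, defaultExchangeable
    m <- rbind(
      c("GLC",    "D-glucose",                      FALSE, TRUE),
      c("XYL",    "D-xylose",                       FALSE, TRUE),
      c("G6P",    "glucose-6-phosphate",            FALSE, FALSE),
      c("F6P",    "fructose-6-phosphate",           FALSE, FALSE),
      c("F16BP",  "fructose-1,6-bisphosphate",      FALSE, FALSE),
      c("DHAP",   "dihydroxyacetone phosphate",     FALSE, FALSE),
      c("GAP",    "glyceraldehyde-3-phosphate",     FALSE, FALSE),
      c("BPG",    "1,3-bisphosphoglycerate",        FALSE, FALSE),
      c("PG3",    "3-phosphoglycerate",             FALSE, FALSE),
      c("PG2",    "2-phosphoglycerate",             FALSE, FALSE),
      c("PEP",    "phosphoenolpyruvate",            FALSE, FALSE),
      c("PYR",    "pyruvate",                       FALSE, FALSE),
      c("ACALD",  "acetaldehyde",                   FALSE, FALSE),
      c("ETOH",   "ethanol",                        FALSE, TRUE),
      c("AC",     "acetate",                        FALSE, TRUE),
      c("ACCOA",  "acetyl-CoA",                     FALSE, FALSE),
      c("ETAC",   "ethyl acetate",                  FALSE, TRUE),
      c("CIT",    "citrate",                        FALSE, FALSE),
      c("ACON",   "cis-aconitate",                  FALSE, FALSE),
      c("ICIT",   "isocitrate",                     FALSE, FALSE),
      c("AKG",    "2-oxoglutarate",                 FALSE, FALSE),
      c("SUCCOA", "succinyl-CoA",                   FALSE, FALSE),
      c("SUC",    "succinate",                      FALSE, FALSE),
      c("FUM",    "fumarate",                       FALSE, FALSE),
      c("MAL",    "malate",                         FALSE, FALSE),
      c("OAA",    "oxaloacetate",                   FALSE, FALSE),
      c("GLX",    "glyoxylate",                     FALSE, FALSE),
      c("GL6P",   "6-phosphogluconolactone",        FALSE, FALSE),
      c("PG6",    "6-phosphogluconate",             FALSE, FALSE),
      c("RU5P",   "ribulose-5-phosphate",           FALSE, FALSE),
      c("R5P",    "ribose-5-phosphate",             FALSE, FALSE),
      c("X5P",    "xylulose-5-phosphate",           FALSE, FALSE),
      c("S7P",    "sedoheptulose-7-phosphate",      FALSE, FALSE),
      c("E4P",    "erythrose-4-phosphate",          FALSE, FALSE),
      c("XYLT",   "xylitol",                        FALSE, TRUE),
      c("XYLU",   "D-xylulose",                     FALSE, FALSE),
      c("G3P",    "glycerol-3-phosphate",           FALSE, FALSE),
      c("GLYC",   "glycerol",                       FALSE, TRUE),
      c("FFA",    "generic fatty acid",             FALSE, TRUE),
      c("FACOA",  "generic fatty acyl-CoA",         FALSE, FALSE),
      c("ENOCOA", "trans-2-enoyl-CoA",              FALSE, FALSE),
      c("HACOA",  "3-hydroxyacyl-CoA",              FALSE, FALSE),
      c("KACOA",  "3-ketoacyl-CoA",                 FALSE, FALSE),
      c("LPAM",   "lipoamide (oxidised)",           FALSE, FALSE),
      c("ACLPAM", "S-acetyl-dihydrolipoamide",      FALSE, FALSE),
      c("DHLPAM", "dihydrolipoamide",               FALSE, FALSE),
      c("PI",     "orthophosphate",                 TRUE,  TRUE),
      c("ATP",    "ATP",                            TRUE,  FALSE),
      c("ADP",    "ADP",                            TRUE,  FALSE),
      c("NAD",    "NAD+",                           TRUE,  FALSE),
      c("NADH",   "NADH",                           TRUE,  FALSE),
      c("NADP",   "NADP+",                          TRUE,  FALSE),
      c("NADPH",  "NADPH",                          TRUE,  FALSE),
      c("COA",    "coenzyme A",                     TRUE,  FALSE),
      c("O2",     "oxygen",                         FALSE, TRUE),
      c("CO2",    "carbon dioxide",                 FALSE, TRUE),
      c("H2O",    "water",                          FALSE, TRUE),
      c("BIOMASS","biomass",                        FALSE, TRUE))
    data.frame(id = m[, 1], name = m[, 2],
               isCofactor = as.logical(m[, 3]),
               defaultExchangeable = as.logical(m[, 4]),
               stringsAsFactors = FALSE)
}

.kmReactionDefs <- function() {
    ## id, metacycId, index, reversible, equation
    list(
 list("GPD",   "1.1.1.8-RXN",        1L, FALSE, "DHAP + NADH -> G3P + NAD"),
 list("TKT1",  "1TRANSKETO-RXN",     2L, TRUE,  "X5P + R5P <-> S7P + GAP"),
 list("OGDH",  "2OXOGLUTARATEDEH-RXN",3L,FALSE, "AKG + NAD + COA -> SUCCOA + NADH + CO2"),
 list("ENO",   "2PGADEHYDRAT-RXN",   4L, TRUE,  "PG2 <-> PEP + H2O"),
 list("TKT2",  "2TRANSKETO-RXN",     5L, TRUE,  "X5P + E4P <-> F6P + GAP"),
 list("PGM",   "3PGAREARR-RXN",      6L, TRUE,  "PG3 <-> PG2"),
 list("PFK",   "6PFRUCTPHOS-RXN",    7L, FALSE, "F6P + ATP -> F16BP + ADP"),
 list("GND",   "6PGLUCONDEHYDROG-RXN",8L,FALSE, "PG6 + NADP -> RU5P + CO2 + NADPH"),
 list("SOL",   "6PGLUCONOLACT-RXN",  9L, FALSE, "GL6P + H2O -> PG6"),
 list("ACS",   "ACETATE--COA-LIGASE-RXN",10L,FALSE,
      "AC + 2 ATP + COA -> ACCOA + 2 ADP + 2 PI"),
 list("ACO1",  "ACONITATEDEHYDR-RXN",11L, TRUE, "CIT <-> ACON + H2O"),
 list("ACO2",  "ACONITATEHYDR-RXN",  12L, TRUE, "ACON + H2O <-> ICIT"),
 list("FAA",   "ACYLCOASYN-RXN",     13L, FALSE,
      "FFA + COA + 2 ATP -> FACOA + 2 ADP + 2 PI"),
 list("ADH",   "ALCOHOL-DEHYDROG-RXN",14L,TRUE, "ACALD + NADH <-> ETOH + NAD"),
 list("CS",    "CITSYN-RXN",         15L, FALSE,
      "ACCOA + OAA + H2O -> CIT + COA"),
 list("XDH",   "D-XYLULOSE-REDUCTASE-RXN",16L,TRUE,
      "XYLT + NAD <-> XYLU + NADH"),
 list("ECH",   "ENOYL-COA-HYDRAT-RXN",17L,TRUE, "ENOCOA + H2O <-> HACOA"),
 list("FBA",   "F16ALDOLASE-RXN",    18L, TRUE, "F16BP <-> DHAP + GAP"),
 list("FBP",   "F16BDEPHOS-RXN",     19L, FALSE, "F16BP + H2O -> F6P + PI"),
 list("FUMH",  "FUMHYDR-RXN",        20L, TRUE, "FUM + H2O <-> MAL"),
 list("GAPDH", "GAPOXNPHOSPHN-RXN",  21L, TRUE, "GAP + NAD + PI <-> BPG + NADH"),
 list("G6PDH", "GLU6PDEHYDROG-RXN",  22L, FALSE, "G6P + NADP -> GL6P + NADPH"),
 list("GLK",   "GLUCOKIN-RXN",       23L, FALSE, "GLC + ATP -> G6P + ADP"),
 list("GPP",   "GLYCEROL-1-PHOSPHATASE-RXN",24L,FALSE,
      "G3P + H2O -> GLYC + PI"),
 list("ICL",   "ISOCIT-CLEAV-RXN",   25L, FALSE, "ICIT -> SUC + GLX"),
 list("IDP",   "ISOCITDEH-RXN",      26L, FALSE,
      "ICIT + NADP -> AKG + CO2 + NADPH"),
 list("IDH",   "ISOCITRATE-DEHYDROGENASE-NAD+-RXN",27L,FALSE,
      "ICIT + NAD -> AKG + CO2 + NADH"),
 list("KAT",   "KETOACYLCOATHIOL-RXN",28L,FALSE, "KACOA + COA -> 2 ACCOA"),
 list("MDH",   "MALATE-DEH-RXN",     29L, TRUE, "MAL + NAD <-> OAA + NADH"),
 list("MAE",   "MALIC-NADP-RXN",     30L, FALSE,
      "MAL + NADP -> PYR + CO2 + NADPH"),
 list("MLS",   "MALSYN-RXN",         31L, FALSE,
      "GLX + ACCOA + H2O -> MAL + COA"),
 list("HADH",  "OHACYL-COA-DEHYDROG-RXN",32L,TRUE,
      "HACOA + NAD <-> KACOA + NADH"),
 list("PPC",   "PEPCARBOX-RXN",      33L, FALSE,
      "PEP + CO2 + H2O -> OAA + PI"),
 list("PCK",   "PEPCARBOXYKIN-RXN",  34L, FALSE,
      "OAA + ATP -> PEP + CO2 + ADP"),
 list("PYK",   "PEPDEPHOS-RXN",      35L, FALSE, "PEP + ADP -> PYR + ATP"),
 list("PPS",   "PEPSYNTH-RXN",       36L, FALSE,
      "PYR + 2 ATP + H2O -> PEP + 2 ADP + PI"),
 list("PGI",   "PGLUCISOM-RXN",      37L, TRUE, "G6P <-> F6P"),
 list("PGK",   "PHOSGLYPHOS-RXN",    38L, TRUE, "BPG + ADP <-> PG3 + ATP"),
 list("PYC",   "PYRUVATE-CARBOXYLASE-RXN",39L,FALSE,
      "PYR + CO2 + ATP + H2O -> OAA + ADP + PI"),
 list("RKI",   "RIB5PISOM-RXN",      40L, TRUE, "RU5P <-> R5P"),
 list("RPE",   "RIBULP3EPIM-RXN",    41L, TRUE, "RU5P <-> X5P"),
 list("PDH_E3","RXN0-1132",          42L, FALSE, "DHLPAM + NAD -> LPAM + NADH"),
 list("PDH_E2","RXN0-1133",          43L, FALSE,
      "ACLPAM + COA -> ACCOA + DHLPAM"),
 list("PDH_E1","RXN0-1134",          44L, FALSE, "PYR + LPAM -> ACLPAM + CO2"),
 list("POX",   "RXN-11026",          45L, FALSE,
      "FACOA + 0.5 O2 -> ENOCOA + H2O"),
 list("PDC",   "RXN-6161",           46L, FALSE, "PYR -> ACALD + CO2"),
 list("ALD",   "RXN66-3",            47L, FALSE,
      "ACALD + NAD + H2O -> AC + NADH"),
 list("XR",    "RXN-8773",           48L, FALSE,
      "XYL + NADPH -> XYLT + NADP"),
 list("SCS",   "SUCCCOASYN-RXN",     49L, TRUE,
      "SUCCOA + ADP + PI <-> SUC + ATP + COA"),
 list("SDH",   "SUCCINATE-DEHYDROGENASE-UBIQUINONE-RXN",50L,FALSE,
      "SUC + 0.5 O2 + 1.5 ADP + 1.5 PI -> FUM + 1.5 ATP + H2O"),
 list("TAL",   "TRANSALDOL-RXN",     51L, TRUE, "S7P + GAP <-> E4P + F6P"),
 list("TPI",   "TRIOSEPISOMERIZATION-RXN",52L,TRUE, "DHAP <-> GAP"),
 list("vETC",  "vETC",               53L, FALSE,
      "NADH + 0.5 O2 + 2.5 ADP + 2.5 PI -> NAD + 2.5 ATP + H2O"),
 list("vEtAc", "vEthylAcetate",      54L, FALSE,
      "ACCOA + ETOH -> ETAC + COA"),
 list("vGrowth","vGrowth",           55L, FALSE, NA_character_),
 list("XKS",   "XYLULOKIN-RXN",      56L, FALSE, "XYLU + ATP -> X5P + ADP"))
}

#' Packaged biomass coefficient sets
#'
#' Returns a [BiomassSpec-class].  The only packaged set, `"standin"`, is a
#' documented synthetic stand-in assembled from textbook-style precursor
#' demands (mmol per gram of cells) folded onto this model's precursor list;
#' the hexose-phosphate demand is carried entirely by glucose-6-phosphate
#' (cell-wall glucans and mannans derive from it).  NADH is produced (not
#' consumed) by net biosynthesis, hence its negative drain.  The coefficients
#' set the scale of the growth flux, which is reported in arbitrary
#' comparative units; all qualitative scenario outcomes are robust to
#' +/-20 percent perturbation of this set (see [perturbBiomass()]).
#'
#' @param set name of the coefficient set (`"standin"`).
#' @return a [BiomassSpec-class].
#' @export
biomassSpec <- function(set = "standin") {
    if (!identical(set, "standin"))
        stop("unknown biomass set '", set,
             "'; only the synthetic 'standin' set is packaged")
    new("BiomassSpec",
        drains = c(G6P = 0.276, R5P = 0.898, E4P = 0.361, GAP = 0.129,
                   PG3 = 1.496, PEP = 0.519, PYR = 2.833, ACCOA = 3.748,
                   OAA = 1.787, AKG = 1.079,
                   NADPH = 16.0, ATP = 41.7, NADH = -3.547),
        provenance = "standin")
}

.growthEquation <- function(drains) {
    stoich <- c(-drains[setdiff(names(drains), c("ATP", "NADPH", "NADH"))],
                ATP = -unname(drains[["ATP"]]),
                ADP = unname(drains[["ATP"]]),
                PI = unname(drains[["ATP"]]),
                NADPH = -unname(drains[["NADPH"]]),
                NADP = unname(drains[["NADPH"]]),
                NADH = -unname(drains[["NADH"]]),
                NAD = unname(drains[["NADH"]]),
                BIOMASS = 1)
    if ("ACCOA" %in% names(drains))
        stoich["COA"] <- unname(drains[["ACCOA"]])
    deparseEquation(stoich[stoich != 0], reversible = FALSE)
}

#' Build the 56-reaction reference model
#'
#' Assembles the packaged central-metabolism reconstruction of
#' *K. marxianus*.  Reaction stoichiometries are transcribed from the MetaCyc
#' reactions named in the model map (the `metacycId` column); display indices
#' 1--56 follow the map legend.  The growth reaction embeds the supplied
#' biomass drains; electron transport is lumped at P/O 2.5.
#'
#' @param biomass a [BiomassSpec-class]; defaults to [biomassSpec()].
#' @return a \linkS4class{StoichiometricModel} with exactly 56 reactions.
#' @examples
#' mod <- buildReferenceModel()
#' nrow(reactions(mod))
#' @export
buildReferenceModel <- function(biomass = biomassSpec()) {
    v <- validObject(biomass, test = TRUE)
    if (!isTRUE(v))
        stop("invalid biomass spec: ", v)
    defs <- .kmReactionDefs()
    rxn <- data.frame(
        id = vapply(defs, `[[`, "", 1L),
        metacycId = vapply(defs, `[[`, "", 2L),
        index = vapply(defs, `[[`, 0L, 3L),
        reversible = vapply(defs, `[[`, NA, 4L),
        equation = vapply(defs, `[[`, "", 5L),
        stringsAsFactors = FALSE)
    rxn$equation[rxn$id == "vGrowth"] <- .growthEquation(biomass@drains)
    rxn$lb <- ifelse(rxn$reversible, -Inf, 0)
    rxn$ub <- Inf
    newStoichiometricModel(.kmMetabolites(), rxn,
                           constants = list(poRatio = 2.5, uptakeBound = 10),
                           biomass = biomass)
}
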