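#' Curated sphingomyelin/ceramide pathway model
#'
#' The bundled curation of the sphingolipid subsystem: 18 enzymatic reactions
#' catalyzed by 35 enzymes, spanning de novo ceramide synthesis (serine +
#' palmitoyl-CoA through 3-ketosphinganine, sphinganine and dihydroceramide),
#' sphingomyelin synthesis/hydrolysis, and the degradative/exit routes through
#' sphinganine-1-phosphate, ceramide-1-phosphate, sphingomyelin,
#' glycosphingolipids, and sphingosine-1-phosphate. Boundary transport is
#' modelled by flagged exchange/demand pseudo-reactions (serine and
#' palmitoyl-CoA sources; sinks for each exit product), which do not count
#' toward the 18 enzymatic steps.
#'
#' Enzyme-step letters follow the conventional A-K labelling of the pathway
#' diagram: A serine palmitoyltransferase, B 3-ketosphinganine reductase,
#' C ceramide synthase, D dihydroceramide desaturase, E ceramidase,
#' F ceramide kinase, G sphingomyelin synthase, H sphingomyelinase,
#' I sphingosine kinase, J S1P phosphatase, K S1P lyase; the
#' glycosphingolipid branch carries no letter.
#'
#' The default objective places equal weight on the four exit-route demand
#' reactions (ceramide-1-phosphate, sphingomyelin, glycosphingolipid, and the
#' S1P-lyase products), so flux analysis rewards total pathway throughput.
#'
#' @return A validated [pathway_model()] with 35 genes and 18 enzymatic
#'   reactions.
#' @examples
#' m <- bundled_sm_model()
#' length(m$genes)                 # 35
#' sum(!m$reactions$pseudo)        # 18
#' @export
bundled_sm_model <- function() {
  mets <- data.frame(
    id = c("ser", "palmcoa", "3ksa", "sphinganine", "dhcer", "cer",
           "sphingosine", "sa1p", "c1p", "sm", "s1p", "glccer", "laccer",
           "galcer", "hexadecenal", "pethanolamine"),
    name = c("L-serine", "palmitoyl-CoA", "3-ketosphinganine", "sphinganine",
             "dihydroceramide", "ceramide", "sphingosine",
             "sphinganine-1-phosphate", "ceramide-1-phosphate",
             "sphingomyelin", "sphingosine-1-phosphate", "glucosylceramide",
             "lactosylceramide", "galactosylceramide", "hexadecenal",
             "phosphoethanolamine"),
    compartment = "c",
    stringsAsFactors = FALSE)

  cers_rule <- "CERS1 or CERS2 or CERS3 or CERS4 or CERS5 or CERS6"
  sphk_rule <- "SPHK1 or SPHK2"
  rxn <- function(id, label, st, rule, rev = FALSE, pseudo = FALSE) {
    list(id = id, label = label, st = st, rule = rule, rev = rev,
         pseudo = pseudo)
  }
  defs <- list(
    rxn("SPT", "A", c(ser = -1, palmcoa = -1, `3ksa` = 1),
        "(SPTLC1 and SPTLC2) or (SPTLC1 and SPTLC3)"),
    rxn("KSR", "B", c(`3ksa` = -1, sphinganine = 1), "KDSR"),
    rxn("CERS_DN", "C", c(sphinganine = -1, dhcer = 1), cers_rule),
    rxn("DES", "D", c(dhcer = -1, cer = 1), "DEGS1"),
    rxn("SPHK_SA", "I", c(sphinganine = -1, sa1p = 1), sphk_rule),
    rxn("CDASE", "E", c(cer = -1, sphingosine = 1),
        "ACER1 or ACER2 or ASAH1 or ASAH2"),
    rxn("CERS_SALV", "C", c(sphingosine = -1, cer = 1), cers_rule),
    rxn("CERK", "F", c(cer = -1, c1p = 1), "CERK"),
    rxn("SMS", "G", c(cer = -1, sm = 1), "SGMS1 or SGMS2", rev = TRUE),
    rxn("SMASE", "H", c(sm = -1, cer = 1),
        "SMPD1 or SMPD2 or SMPD3 or ENPP7"),
    rxn("SPHK", "I", c(sphingosine = -1, s1p = 1), sphk_rule),
    rxn("SGPP", "J", c(s1p = -1, sphingosine = 1),
        "SGPP1 or SGPP2 or PLPP2"),
    rxn("SGPL", "K", c(s1p = -1, hexadecenal = 1, pethanolamine = 1),
        "SGPL1"),
    rxn("UGCG", NA, c(cer = -1, glccer = 1), "UGCG"),
    rxn("GCDASE", NA, c(glccer = -1, cer = 1), "GBA or GBA2"),
    rxn("LACCS", NA, c(glccer = -1, laccer = 1), "B4GALT5 or B4GALT6"),
    rxn("CGT", NA, c(cer = -1, galcer = 1), "UGT8"),
    rxn("GALCDASE", NA, c(galcer = -1, cer = 1), "GALC"),
    # boundary pseudo-reactions: substrate sources and exit-route sinks
    rxn("EX_ser", NA, c(ser = 1), NA, pseudo = TRUE),
    rxn("EX_palmcoa", NA, c(palmcoa = 1), NA, pseudo = TRUE),
    rxn("DM_sa1p", NA, c(sa1p = -1), NA, pseudo = TRUE),
    rxn("DM_c1p", NA, c(c1p = -1), NA, pseudo = TRUE),
    rxn("DM_sm", NA, c(sm = -1), NA, pseudo = TRUE),
    rxn("DM_laccer", NA, c(laccer = -1), NA, pseudo = TRUE),
    rxn("DM_hexadecenal", NA, c(hexadecenal = -1), NA, pseudo = TRUE),
    rxn("DM_pethanolamine", NA, c(pethanolamine = -1), NA, pseudo = TRUE)
  )
  rxns <- do.call(rbind, lapply(defs, function(d) {
    data.frame(id = d$id, label = d$label, reversible = d$rev,
               lb = if (d$rev) -1000 else 0, ub = 1000,
               gene_rule = d$rule, pseudo = d$pseudo,
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(defs, `[[`, "st")
  names(stoich) <- rxns$id
  objective <- data.frame(
    rxn = c("DM_c1p", "DM_sm", "DM_laccer", "DM_hexadecenal"),
    weight = 1, stringsAsFactors = FALSE)
  pathway_model(mets, rxns, stoich, objective)
}
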