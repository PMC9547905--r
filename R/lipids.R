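#' Parse lipid shorthand nomenclature
#'
#' Parses names of the form `CLASS(dC:D)` (total carbons:double bonds over a
#' sphingoid base assumed d18:1 when no explicit split is given) or
#' `CLASS(dB:Y/A:Z)` (explicit base/N-acyl split), e.g. `"SM(d34:1)"`,
#' `"SM (d43:1)"`, `"Cer(d18:1/16:0)"`. The N-acyl chain length is
#' `total - base` carbons; species with acyl chains shorter than `chain_cut`
#' carbons are classed `short`, the rest `long`.
#'
#' @param name Character vector of lipid names.
#' @param chain_cut Acyl-carbon threshold between short and long chains
#'   (default 20, i.e. short means < C20).
#' @return data.frame with one row per name: `raw_name`, `lipid_class`,
#'   `base_carbons`, `base_double_bonds`, `total_carbons`,
#'   `total_double_bonds`, `acyl_carbons`, `chain_class`.
#' @examples
#' parse_lipid_name(c("SM(d34:1)", "SM(d43:1)"))
#' @export
parse_lipid_name <- function(name, chain_cut = 20) {
  pat <- "^([A-Za-z][A-Za-z0-9-]*)\\s*\\(\\s*d(\\d+):(\\d+)(?:\\s*/\\s*(\\d+):(\\d+))?\\s*\\)$"
  out <- lapply(name, function(nm) {
    m <- regmatches(nm, regexec(pat, nm))[[1]]
    if (length(m) == 0L) {
      stop("cannot parse lipid name '", nm, "': expected CLASS(dC:D) or ",
           "CLASS(dB:Y/A:Z)", call. = FALSE)
    }
    cls <- m[2]
    c1 <- as.integer(m[3]); d1 <- as.integer(m[4])
    if (nzchar(m[5])) {
      base_c <- c1; base_d <- d1
      acyl_c <- as.integer(m[5]); acyl_d <- as.integer(m[6])
      tot_c <- base_c + acyl_c; tot_d <- base_d + acyl_d
    } else {
      base_c <- 18L; base_d <- 1L
      tot_c <- c1; tot_d <- d1
      acyl_c <- tot_c - base_c
    }
    if (acyl_c < 0L) {
      stop("lipid '", nm, "': total carbons below the d18 sphingoid base",
           call. = FALSE)
    }
    data.frame(raw_name = nm, lipid_class = cls, base_carbons = base_c,
               base_double_bonds = base_d, total_carbons = tot_c,
               total_double_bonds = tot_d, acyl_carbons = acyl_c,
               chain_class = if (acyl_c < chain_cut) "short" else "long",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Enumerate ratio traits over a species panel
#'
#' `mode = "all"` builds every single-species trait plus every ordered ratio
#' of two distinct species (so 112 species yield 112 + 112 x 111 = 12,544
#' traits). `mode = "targeted"` builds only short-chain / long-chain
#' sphingomyelin ratios, one orientation per pair (short numerator over long
#' denominator).
#'
#' @param species Character vector of lipid names (parseable by
#'   [parse_lipid_name()]).
#' @param mode `"all"` or `"targeted"`.
#' @param chain_cut Acyl-carbon short/long threshold (default 20).
#' @return data.frame with columns `trait`, `type` (`"single"`/`"ratio"`),
#'   `numerator`, `denominator` (`NA` for singles).
#' @export
enumerate_traits <- function(species, mode = c("targeted", "all"),
                             chain_cut = 20) {
  mode <- match.arg(mode)
  stopifnot(length(species) >= 1, !anyDuplicated(species))
  info <- parse_lipid_name(species, chain_cut)
  if (mode == "all") {
    singles <- data.frame(trait = species, type = "single",
                          numerator = species, denominator = NA_character_,
                          stringsAsFactors = FALSE)
    if (length(species) > 1) {
      pairs <- expand.grid(numerator = species, denominator = species,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$numerator != pairs$denominator, ]
      ratios <- data.frame(
        trait = paste0(pairs$numerator, "/", pairs$denominator),
        type = "ratio", numerator = pairs$numerator,
        denominator = pairs$denominator, stringsAsFactors = FALSE)
    } else {
      ratios <- NULL
    }
    out <- rbind(singles, ratios)
  } else {
    sm <- info[info$lipid_class == "SM", ]
    short <- sm$raw_name[sm$chain_class == "short"]
    long <- sm$raw_name[sm$chain_class == "long"]
    if (length(short) == 0L || length(long) == 0L) {
      out <- data.frame(trait = character(), type = character(),
                        numerator = character(), denominator = character(),
                        stringsAsFactors = FALSE)
    } else {
      pairs <- expand.grid(numerator = short, denominator = long,
                           stringsAsFactors = FALSE)
      out <- data.frame(
        trait = paste0(pairs$numerator, "/", pairs$denominator),
        type = "ratio", numerator = pairs$numerator,
        denominator = pairs$denominator, stringsAsFactors = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-sample trait values
#'
#' Single-species traits are `log2(abundance)`; ratio traits are
#' `log2(numerator / denominator)`.
#'
#' @param abundances Positive numeric matrix, samples x species (column
#'   names = lipid names).
#' @param traits data.frame from [enumerate_traits()].
#' @return Numeric matrix, samples x traits (column names = `traits$trait`).
#' @export
trait_values <- function(abundances, traits) {
  x <- as.matrix(abundances)
  if (any(x <= 0, na.rm = TRUE)) {
    stop("abundances must be positive for log transformation", call. = FALSE)
  }
  lx <- log2(x)
  vals <- matrix(NA_real_, nrow(x), nrow(traits),
                 dimnames = list(rownames(x), traits$trait))
  for (i in seq_len(nrow(traits))) {
    if (traits$type[i] == "single") {
      vals[, i] <- lx[, traits$numerator[i]]
    } else {
      vals[, i] <- lx[, traits$numerator[i]] - lx[, traits$denominator[i]]
    }
  }
  vals
}
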