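#' Read a numeric TSV matrix
#'
#' First column is taken as row names; every remaining cell must be numeric.
#'
#' @param path TSV file path.
#' @return Numeric matrix.
#' @export
read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  rn <- df[[1]]
  df <- df[, -1, drop = FALSE]
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suspect <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop("non-numeric cell in ", path, " at row '", rn[suspect],
           "', column '", colnames(df)[j], "'", call. = FALSE)
    }
  }
  m <- as.matrix(df)
  rownames(m) <- rn
  m
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file into an additive dosage matrix.
#' Positions stay 1-based in the variant table (VCF convention); interval
#' logic elsewhere converts to 0-based half-open internally. Multi-allelic
#' records are rejected by default; mixed-ploidy GT entries are always
#' rejected.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param multiallelic `"reject"` (default, error) or `"drop"` (remove with
#'   a message).
#' @return List with `variants` (data.frame `chrom`, `pos`, `id`, `ref`,
#'   `alt`) and `dosage` (samples x variants, 0/1/2/NA).
#' @export
read_vcf <- function(path, multiallelic = c("reject", "drop")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fx$ALT)
  if (any(multi)) {
    if (multiallelic == "reject") {
      stop("multi-allelic record(s) in ", path, " (e.g. ",
           fx$CHROM[multi][1], ":", fx$POS[multi][1],
           "); pass multiallelic = \"drop\" to remove them", call. = FALSE)
    }
    message("dropping ", sum(multi), " multi-allelic record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fx <- fx[keep, , drop = FALSE]
  gt_chr <- gsub("\\|", "/", gt)
  ok <- is.na(gt_chr) | gt_chr %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (!all(ok)) {
    stop("unsupported GT value(s) in ", path, ": ",
         paste(unique(gt_chr[!ok]), collapse = ", "), call. = FALSE)
  }
  dos <- matrix(NA_real_, nrow(gt_chr), ncol(gt_chr),
                dimnames = dimnames(gt_chr))
  dos[gt_chr == "0/0"] <- 0
  dos[gt_chr %in% c("0/1", "1/0")] <- 1
  dos[gt_chr == "1/1"] <- 2
  ids <- fx$ID
  ids[is.na(ids) | ids == "."] <- paste0(fx$CHROM, ":", fx$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS),
                         id = ids, ref = fx$REF, alt = fx$ALT,
                         stringsAsFactors = FALSE)
  dosage <- t(dos)
  colnames(dosage) <- variants$id
  list(variants = variants, dosage = dosage)
}

#' Write genotypes to a minimal VCF 4.2 file
#' @param geno List with `variants` and `dosage` (as in [read_vcf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  dos <- geno$dosage
  gt <- matrix("./.", ncol(dos), nrow(dos))
  gt[t(dos) == 0] <- "0/0"
  gt[t(dos) == 1] <- "0/1"
  gt[t(dos) == 2] <- "1/1"
  lines <- c("##fileformat=VCFv4.2",
             "##source=sphingolens",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(dos)), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read gene regions from a BED file
#'
#' 4-column BED (chrom, start, end, name), 0-based half-open, kept in that
#' convention internally.
#'
#' @param path BED file path.
#' @return data.frame with `gene`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED file needs 4 columns (chrom, start, end, ",
                         "name): ", path, call. = FALSE)
  out <- data.frame(gene = df[[4]], chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) {
    stop("BED interval with start >= end in ", path, call. = FALSE)
  }
  out
}

#' Write gene regions to BED
#' @param regions data.frame with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a matrix as TSV with a provenance header comment
#' @param m Matrix or data.frame.
#' @param path Output path.
#' @param provenance Optional named list folded into a `#` header line.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", paste(names(provenance), unlist(provenance),
                                  sep = "=", collapse = " ")), con)
  }
  df <- as.data.frame(m)
  df <- cbind(id = rownames(m) %||% seq_len(nrow(df)), df)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' Write a simulated dataset to a ready-to-run directory
#'
#' Emits the TSV/VCF/BED/JSON dialects the pipeline readers consume, plus a
#' `truth.json` planted-effect ledger.
#'
#' @param sim Output of [simulate_expression()], [simulate_panel()], or
#'   [simulate_genotypes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(package = "sphingolens", seed = sim$truth$seed)
  if (sim$truth$kind == "expression") {
    expr <- do.call(cbind, sim$profiles)
    write_tsv_matrix(expr, file.path(dir, "expression.tsv"), prov)
    utils::write.table(
      data.frame(sample_id = names(sim$diagnosis),
                 diagnosis = unname(sim$diagnosis)),
      file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  } else if (sim$truth$kind == "panel") {
    write_tsv_matrix(sim$abundances, file.path(dir, "abundances.tsv"), prov)
    write_tsv_matrix(cbind(sim$covariates),
                     file.path(dir, "covariates.tsv"), prov)
    write_tsv_matrix(cbind(sim$medications),
                     file.path(dir, "medications.tsv"), prov)
    write_tsv_matrix(cbind(sim$phenotypes),
                     file.path(dir, "phenotypes.tsv"), prov)
  } else if (sim$truth$kind == "genotypes") {
    write_vcf(sim$geno, file.path(dir, "genotypes.vcf"))
    write_tsv_matrix(cbind(phenotype = sim$phenotype, sim$covariates),
                     file.path(dir, "phenotype.tsv"), prov)
  } else {
    stop("unknown simulation kind", call. = FALSE)
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run a full pipeline arm from a configuration list
#'
#' Thin orchestration over the arm functions: reads the configured inputs,
#' runs the arm, and writes tidy TSV outputs plus a `provenance.json`
#' (package version, timestamp, seed, config hash) and a `log.txt` with
#' before/after filter counts. Outputs are deterministic given the config.
#'
#' @param config List with `arm` (`"flux"`, `"ratios"`, or `"genetics"`),
#'   `out` (output directory), `seed`, and arm-specific entries:
#'   \describe{
#'     \item{flux}{`model` (JSON path; `NULL` = bundled curation),
#'       `expression` (TSV genes x samples), `samples` (TSV sample sheet),
#'       optional `q_low`, `q_high`, `epsilon`.}
#'     \item{ratios}{`abundances`, `covariates`, `medications` (TSVs),
#'       `phenotypes` TSV with the column named by `phenotype`, `mode`,
#'       optional `chain_cut`.}
#'     \item{genetics}{`vcf`, `bed`, `phenotype` (TSV: first column sample
#'       id, column `phenotype` plus covariates), optional `profile`
#'       (`"adni1"`/`"adni2"`), `flank`, `B`.}
#'   }
#' @return Invisible list of the arm's in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$arm), !is.null(config$out))
  arm <- match.arg(config$arm, c("flux", "ratios", "genetics"))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  logf <- file.path(out, "log.txt")
  logline <- function(...) cat(..., "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  need <- function(p) {
    if (is.null(p) || !file.exists(p)) {
      stop("input file not found: ", p %||% "<missing>", call. = FALSE)
    }
    p
  }
  prov <- list(package = "sphingolens",
               version = as.character(utils::packageVersion("sphingolens")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               seed = seed,
               config_hash = config_hash(config[setdiff(names(config),
                                                        "out")]),
               arm = arm)
  # header stamped into output tables; no timestamp so reruns are identical
  hdr <- prov[c("package", "version", "seed", "config_hash", "arm")]

  result <- if (arm == "flux") {
    model <- if (is.null(config$model)) {
      bundled_sm_model()
    } else {
      load_model(need(config$model))
    }
    expr <- read_tsv_matrix(need(config$expression))
    sheet <- utils::read.delim(need(config$samples),
                               stringsAsFactors = FALSE)
    profiles <- lapply(colnames(expr), function(s) expr[, s])
    names(profiles) <- colnames(expr)
    diagnosis <- sheet$diagnosis[match(names(profiles), sheet$sample_id)]
    logline("samples: ", length(profiles), "; reactions: ",
            nrow(model$reactions))
    res <- run_flux_diff(model, profiles, diagnosis,
                         q_low = config$q_low %||% 0.25,
                         q_high = config$q_high %||% 0.75,
                         epsilon = config$epsilon %||% 1)
    write_tsv_matrix(res$flux$v_max, file.path(out, "flux_max.tsv"), hdr)
    write_tsv_matrix(res$flux$v_min, file.path(out, "flux_min.tsv"), hdr)
    write_tsv_matrix(res$comparison, file.path(out, "comparison.tsv"), hdr)
    logline("significant reaction-pair tests: ",
            sum(res$comparison$significant))
    res
  } else if (arm == "ratios") {
    panel <- list(
      abundances = read_tsv_matrix(need(config$abundances)),
      covariates = as.data.frame(read_tsv_matrix(need(config$covariates))),
      medications = if (!is.null(config$medications)) {
        as.data.frame(read_tsv_matrix(config$medications))
      },
      phenotypes = as.data.frame(read_tsv_matrix(need(config$phenotypes))))
    logline("species: ", ncol(panel$abundances), "; samples: ",
            nrow(panel$abundances))
    res <- run_screen(panel, phenotype = config$phenotype %||% "cognition",
                      mode = config$mode %||% "all",
                      chain_cut = config$chain_cut %||% 20)
    logline("traits tested: ", nrow(res), "; BH-significant: ",
            sum(res$significant, na.rm = TRUE))
    write_tsv_matrix(res, file.path(out, "screen.tsv"), hdr)
    res
  } else {
    geno <- read_vcf(need(config$vcf))
    regions <- read_bed(need(config$bed))
    ph <- utils::read.delim(need(config$phenotype), comment.char = "#",
                            stringsAsFactors = FALSE)
    ids <- ph[[1]]
    y <- ph$phenotype[match(rownames(geno$dosage), ids)]
    covars <- ph[match(rownames(geno$dosage), ids),
                 setdiff(colnames(ph), c(colnames(ph)[1], "phenotype")),
                 drop = FALSE]
    thr <- qc_profile(config$profile %||% "adni1")
    prov$qc_profile <- config$profile %||% "adni1"
    prov$thresholds <- thr
    logline("variants before QC: ", ncol(geno$dosage), "; samples: ",
            nrow(geno$dosage))
    qc <- qc_filter(geno, thr$cr_min, thr$hwe_min, thr$maf_min)
    logline("variants after QC: ", ncol(qc$geno$dosage),
            "; samples removed: ", length(qc$samples_removed))
    amap <- assign_variants(qc$geno$variants, regions,
                            flank = config$flank %||% 5000)
    rows <- lapply(names(amap), function(g) {
      block <- qc$geno$dosage[, amap[[g]], drop = FALSE]
      r <- gene_permutation_p(block, y, covars, B = config$B %||% 20000,
                              seed = seed)
      data.frame(gene = g, n_variants = r$n_variants, min_p = r$min_p,
                 bonf_threshold = r$bonferroni_threshold,
                 perm_p = r$perm_p, B = r$B, seed = r$seed,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    write_tsv_matrix(res, file.path(out, "gene_assoc.tsv"), hdr)
    write_tsv_matrix(qc$report, file.path(out, "variant_qc.tsv"), hdr)
    logline("genes tested: ", nrow(res))
    res
  }
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
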