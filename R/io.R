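# File formats.  Dialects are named after the BioNano ecosystem (CMAP for
# site maps, BNX for molecules, XMAP for alignments) but the column layouts
# are pinned by this package; full upstream-format fidelity is not
# promised.  All formats are plain tab-separated text with '#' headers and
# round-trip losslessly.

#' Read reference maps from a FASTA file
#'
#' Digests every record of a (multi-)FASTA with the nicking motif; record
#' ids become telomere ids.
#'
#' @param path FASTA file.
#' @param motif,nick_offset see [in_silico_nick()].
#' @param arm arm assigned to every record (`"p"` or `"q"`).
#' @return named list of `reference_map` objects.
#' @export
read_reference_fasta <- function(path, motif = "GCTCTTC", nick_offset = 0,
                                 arm = "p") {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    id <- sub("\\s.*", "", names(seqs)[i])
    build_reference_map(id, sequence = as.character(seqs[[i]]), arm = arm,
                        motif = motif, nick_offset = nick_offset)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write / read a CMAP-style site map
#'
#' One row per site: map id, map length, number of sites, site index,
#' position.  Map metadata that does not fit the tabular layout (arm, gap
#' intervals, distal offset) goes to a YAML sidecar `<path>.meta.yaml`.
#'
#' @param map a `reference_map` or `consensus_map`.
#' @param path output file.
#' @return `write_cmap`: the path, invisibly.  `read_cmap`: a
#'   `reference_map`.
#' @export
write_cmap <- function(map, path) {
  sites <- map$sites
  len <- if (inherits(map, "reference_map")) map$length
         else max(c(sites, 0))
  id <- if (inherits(map, "reference_map")) map$id else map$tel_id
  df <- data.frame(CMapId = id, ContigLength = len,
                   NumSites = length(sites),
                   SiteID = seq_along(sites), Position = sites)
  con <- file(path, "w")
  writeLines("#h CMapId\tContigLength\tNumSites\tSiteID\tPosition", con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  close(con)
  if (inherits(map, "reference_map")) {
    meta <- list(id = map$id, arm = map$arm,
                 length = map$length,
                 gaps = if (nrow(map$gaps)) apply(map$gaps, 1, as.list,
                                                  simplify = FALSE)
                        else list(),
                 distal_offset = if (is.na(map$distal_offset)) "unknown"
                                 else map$distal_offset)
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' @rdname write_cmap
#' @export
read_cmap <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("CMapId", "ContigLength", "NumSites",
                                 "SiteID", "Position"),
                   stringsAsFactors = FALSE)
  metafile <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(metafile)) yaml::read_yaml(metafile) else NULL
  id <- if (nrow(df)) as.character(df$CMapId[1]) else
    if (!is.null(meta)) meta$id else "map"
  len <- if (nrow(df)) df$ContigLength[1] else meta$length
  gaps <- NULL
  arm <- "p"; doff <- 0
  if (!is.null(meta)) {
    arm <- meta$arm
    doff <- meta$distal_offset
    len <- meta$length
    if (length(meta$gaps))
      gaps <- lapply(meta$gaps, function(g) c(g[[1]], g[[2]]))
  }
  build_reference_map(id, sites = df$Position, length = len, arm = arm,
                      gaps = gaps, distal_offset = doff)
}

#' Write / read molecules in a BNX-style format
#'
#' Per molecule two lines: `0 <id> <length>` and `1 <pos> <pos> ...` (the
#' `1` line is present even when the molecule has no labels).
#'
#' @param mols `molecule_set` or list of [molecule()].
#' @param path file path.
#' @return `write_bnx`: the path, invisibly.  `read_bnx`: a list of
#'   [molecule()].
#' @export
write_bnx <- function(mols, path) {
  ml <- if (inherits(mols, "molecule_set")) mols$molecules else mols
  con <- file(path, "w")
  writeLines("# BNX-style molecule file: 0 id length / 1 label positions",
             con)
  for (m in ml) {
    writeLines(sprintf("0\t%s\t%.2f", m$id, m$length), con)
    writeLines(paste(c("1", sprintf("%.2f", m$labels)), collapse = "\t"),
               con)
  }
  close(con)
  invisible(path)
}

#' @rdname write_bnx
#' @export
read_bnx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    f0 <- strsplit(lines[i], "\t")[[1]]
    stopifnot(f0[1] == "0")
    f1 <- strsplit(lines[i + 1], "\t")[[1]]
    stopifnot(f1[1] == "1")
    labs <- if (length(f1) > 1) as.numeric(f1[-1]) else numeric(0)
    out[[length(out) + 1]] <- molecule(f0[2], as.numeric(f0[3]), labs)
    i <- i + 2
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write simulator truth sidecar
#'
#' @param mols a `molecule_set` with truth.
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
write_molecule_truth <- function(mols, path) {
  stopifnot(inherits(mols, "molecule_set"))
  write.table(mols$truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write alignments in an XMAP-style format
#'
#' One row per alignment: molecule id, reference id, orientation, offset,
#' score, confidence, and the matched pairs as a cigar-like
#' `label:site` comma string.
#'
#' @param alignments list of `om_alignment`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_xmap <- function(alignments, path) {
  alignments <- Filter(is_alignment, alignments)
  con <- file(path, "w")
  writeLines(
    "#h MoleculeID\tRefID\tOrientation\tOffset\tScore\tConfidence\tPairs",
    con)
  for (a in alignments) {
    writeLines(sprintf("%s\t%s\t%s\t%.2f\t%.4f\t%.4f\t%s",
                       a$molecule_id, a$ref_id, a$orientation, a$offset,
                       a$score, a$confidence,
                       paste(sprintf("%d:%d", a$pairs$label, a$pairs$site),
                             collapse = ",")), con)
  }
  close(con)
  invisible(path)
}

#' Write SV calls as BED
#'
#' Reference coordinates, `name = type:code`, `score = supporting molecule
#' count`.
#'
#' @param calls an `sv_calls` data frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_sv_bed <- function(calls, path) {
  if (!nrow(calls)) {
    con <- file(path, "w"); close(con)
    return(invisible(path))
  }
  start <- pmax(0, round(calls$position))
  df <- data.frame(chrom = calls$tel_id, start = start,
                   end = start + pmax(1, round(calls$size)),
                   name = paste0(calls$type, ":", calls$code),
                   score = calls$support)
  con <- file(path, "w")
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  close(con)
  invisible(path)
}

#' Write per-molecule telomere estimates / per-haplotype summaries
#'
#' Estimates are written in bp; summaries mirror the field's tabulation:
#' mean and SD in kb with one decimal, molecule count, and an asterisked
#' telomere id for gap haplotypes (unknown distal offset).
#'
#' @param estimates a `telomere_estimate` data frame.
#' @param summaries a `telomere_summary` data frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_estimates_tsv <- function(estimates, path) {
  write.table(estimates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_tsv
#' @export
write_summary_tsv <- function(summaries, path) {
  df <- data.frame(
    telomere = paste0(summaries$tel_id,
                      ifelse(summaries$gap, "*", "")),
    haplotype = summaries$haplotype,
    mean_kb = sprintf("%.1f", summaries$mean / 1000),
    sd_kb = ifelse(is.na(summaries$sd), "",
                   sprintf("%.1f", summaries$sd / 1000)),
    n = summaries$n)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a simulation scenario as YAML
#'
#' A scenario file holds the subtelomere architecture (`spec`), simulation
#' parameters (`params`) and the 1-copy anchoring interval, mirroring the
#' arguments of [subtelomere_spec()] and [sim_params()].  Reading realizes
#' the scenario (sequences are built), so the result can be passed
#' straight to [run_scenario()].
#'
#' @param path YAML file.
#' @return `read_scenario`: a realized `telo_scenario`.  `write_scenario`:
#'   the path, invisibly.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- y$spec
  edits <- lapply(sp$edits, function(hap) lapply(hap, as.list))
  spec <- subtelomere_spec(
    id = sp$id, arm = if (is.null(sp$arm)) "p" else sp$arm,
    tract = as.numeric(sp$tract),
    one_copy_length = if (is.null(sp$one_copy_length)) 150000
                      else sp$one_copy_length,
    edits = edits,
    site_spacing = if (is.null(sp$site_spacing)) 9300 else sp$site_spacing,
    ref_gaps = lapply(sp$ref_gaps, as.numeric),
    distal_unrepresented = if (is.null(sp$distal_unrepresented)) 0
                           else sp$distal_unrepresented,
    distal_offset_known = !isFALSE(sp$distal_offset_known),
    seed = if (is.null(sp$seed)) 1 else sp$seed)
  params <- do.call(sim_params, if (is.null(y$params)) list() else y$params)
  build <- build_diploid_subtelomere(spec)
  structure(list(
    name = if (is.null(y$name)) spec$id else y$name,
    reference = build$reference,
    haplotypes = lapply(build$haplotypes, `[[`, "truth"),
    build = build, params = params,
    one_copy_interval = if (is.null(y$one_copy_interval))
      c(120000, build$reference$length)
    else as.numeric(y$one_copy_interval),
    extra_molecules = list()), class = "telo_scenario")
}

#' @rdname read_scenario
#' @param spec a [subtelomere_spec()].
#' @param params a [sim_params()].
#' @param one_copy_interval `[start, end)` bp anchoring interval.
#' @param name scenario name.
#' @export
write_scenario <- function(spec, params, one_copy_interval, path,
                           name = spec$id) {
  stopifnot(inherits(spec, "subtelomere_spec"),
            inherits(params, "sim_params"))
  y <- list(
    name = name,
    spec = list(id = spec$id, arm = spec$arm, tract = spec$tract,
                one_copy_length = spec$one_copy_length,
                edits = spec$edits, site_spacing = spec$site_spacing,
                ref_gaps = spec$ref_gaps,
                distal_unrepresented = spec$distal_unrepresented,
                distal_offset_known = spec$distal_offset_known,
                seed = spec$seed),
    params = unclass(params),
    one_copy_interval = one_copy_interval)
  yaml::write_yaml(y, path)
  invisible(path)
}
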