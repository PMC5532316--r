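# Readers and writers for the exchange formats: FASTA (+ annotation TSV),
# Affymetrix-style probe tab, GCT/TSV expression, CLS labels, GMT sets,
# and the package's own TSV/JSON outputs. Writers are deterministic byte
# streams: stable column order, floats at 6 significant digits.

#' Read an annotated transcriptome
#'
#' Either a FASTA plus a sidecar TSV (columns \code{transcript_id},
#' \code{gene_id}, \code{biotype}, optional \code{gene_name}), or a single
#' FASTA whose headers carry pipe-delimited fields
#' \code{transcript_id|gene_id|gene_name|biotype}. Sequences are
#' uppercased and U is normalized to T; transcripts with biotypes other
#' than \code{lncRNA}/\code{protein_coding} are dropped with a logged
#' count.
#'
#' @param fasta_path FASTA file path.
#' @param annotation_path optional sidecar TSV path.
#' @return A \code{\link{transcriptSet}}.
#' @export
readTranscripts <- function(fasta_path, annotation_path = NULL) {
  raw <- Biostrings::readBStringSet(fasta_path)
  headers <- names(raw)
  seqs <- as.character(raw)
  if (is.null(annotation_path)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    if (any(lengths(parts) < 4L))
      stop("FASTA header without the 4 pipe-delimited fields ",
           "(transcript_id|gene_id|gene_name|biotype): ",
           headers[which(lengths(parts) < 4L)[1]])
    ann <- data.frame(transcript_id = vapply(parts, `[`, "", 1L),
                      gene_id = vapply(parts, `[`, "", 2L),
                      gene_name = vapply(parts, `[`, "", 3L),
                      biotype = vapply(parts, `[`, "", 4L),
                      stringsAsFactors = FALSE)
  } else {
    ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "gene_id", "biotype")
    miss <- setdiff(need, names(ann))
    if (length(miss))
      stop("annotation missing column(s): ", paste(miss, collapse = ", "))
    ids <- sub("\\s.*$", "", headers)
    absent <- setdiff(ids, ann$transcript_id)
    if (length(absent))
      stop("transcript in FASTA missing from annotation: ",
           paste(absent, collapse = ", "))
    ann <- ann[match(ids, ann$transcript_id), , drop = FALSE]
    if (is.null(ann$gene_name)) ann$gene_name <- ann$gene_id
  }
  if (anyDuplicated(ann$transcript_id))
    stop("duplicate transcript_id: ",
         ann$transcript_id[duplicated(ann$transcript_id)][1])
  transcriptSet(seqs, ann$transcript_id, ann$gene_id, ann$biotype,
                ann$gene_name)
}

#' Write transcripts as FASTA (+ annotation TSV)
#'
#' @param transcripts a \code{\link{transcriptSet}}.
#' @param fasta_path,annotation_path output paths.
#' @return Invisibly, the FASTA path.
#' @export
writeTranscripts <- function(transcripts, fasta_path,
                             annotation_path = NULL) {
  Biostrings::writeXStringSet(transcripts, fasta_path)
  if (!is.null(annotation_path)) {
    meta <- S4Vectors::mcols(transcripts)
    ann <- data.frame(transcript_id = names(transcripts),
                      gene_id = meta$gene_id,
                      gene_name = if (is.null(meta$gene_name)) meta$gene_id
                                  else meta$gene_name,
                      biotype = meta$biotype, stringsAsFactors = FALSE)
    write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Read an Affymetrix-style probe tab file
#'
#' TSV with a header. Default column names are \code{probe_id} and
#' \code{sequence}, remappable via \code{column_map}; when no probe id
#' column exists but \code{probeset_id}, \code{x} and \code{y} do, a
#' composite id \code{probeset_id:x:y} is formed.
#'
#' @param path file path.
#' @param column_map named character, e.g.
#'   \code{c(probe_id = "Probe.ID", sequence = "Probe.Sequence")}.
#' @param probe_length expected probe length; rows with a wrong-length
#'   sequence raise an error naming the probe.
#' @return A \code{\link{probeSet}}.
#' @export
readProbeTab <- function(path,
                         column_map = c(probe_id = "probe_id",
                                        sequence = "sequence"),
                         probe_length = 25L) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  seq_col <- column_map[["sequence"]]
  if (!seq_col %in% names(tab))
    stop("probe tab missing sequence column: ", seq_col)
  id_col <- column_map[["probe_id"]]
  if (!is.null(id_col) && id_col %in% names(tab)) {
    ids <- as.character(tab[[id_col]])
  } else if (all(c("probeset_id", "x", "y") %in% names(tab))) {
    ids <- paste(tab$probeset_id, tab$x, tab$y, sep = ":")
  } else {
    stop("probe tab needs a probe id column (", id_col,
         ") or probeset_id + x + y")
  }
  pset <- if ("probeset_id" %in% names(tab)) tab$probeset_id else NULL
  probeSet(tab[[seq_col]], ids, probeset_id = pset,
           probe_length = probe_length)
}

#' Write a probe tab file
#' @param probes a \code{\link{probeSet}}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeProbeTab <- function(probes, path) {
  tab <- data.frame(probe_id = names(probes),
                    sequence = as.character(probes),
                    stringsAsFactors = FALSE)
  ps <- S4Vectors::mcols(probes)$probeset_id
  if (!is.null(ps)) tab$probeset_id <- ps
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, \code{name TAB description TAB
#' member...}. The description field carries \code{n_instances=K} for
#' drug-induced sets; unparseable descriptions yield count 1. Lines with
#' no members are skipped with a warning; duplicate set names are an
#' error. Write-then-read restores the collection.
#'
#' @param path file path.
#' @return \code{readGmt}: a \linkS4class{DrugSetCollection}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); n_inst <- integer(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      warning("GMT line with no members skipped: ", f[1])
      next
    }
    name <- f[1]
    if (name %in% names(sets)) stop("duplicate set name in GMT: ", name)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      warning("GMT line with no members skipped: ", name)
      next
    }
    sets[[name]] <- members
    k <- suppressWarnings(
      as.integer(sub("^.*n_instances=([0-9]+).*$", "\\1", f[2])))
    n_inst[name] <- if (is.na(k)) 1L else k
  }
  DrugSetCollection(sets, n_inst)
}

#' @rdname readGmt
#' @param x a \linkS4class{DrugSetCollection}.
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "DrugSetCollection"))
  lines <- vapply(names(x@sets), function(d)
    paste(c(d, sprintf("n_instances=%d", x@nInstances[[d]]), x@sets[[d]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write expression matrices (GCT or plain TSV)
#'
#' GCT: \code{#1.2} version line, dims line, then a table with
#' \code{Name}/\code{Description} columns. Plain TSV: first column feature
#' ids, remaining columns samples. \code{readExpression} sniffs the
#' format from the first line.
#'
#' @param path file path.
#' @return A numeric matrix, features x samples.
#' @export
readGct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1], "#1.2"))
    stop("not a GCT 1.2 file: ", path)
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  tab <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2])
    stop(sprintf("GCT dims line says %d x %d but table is %d x %d",
                 dims[1], dims[2], nrow(tab), ncol(tab) - 2L))
  if (anyDuplicated(tab[[1]]))
    stop("duplicate feature id in GCT: ", tab[[1]][duplicated(tab[[1]])][1])
  mat <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(mat) <- tab[[1]]
  storage.mode(mat) <- "double"
  .checkExprMatrix(mat)
}

#' @rdname readGct
#' @param mat numeric matrix to write.
#' @export
writeGct <- function(mat, path) {
  .checkExprMatrix(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  header <- paste(c("Name", "Description", colnames(mat)), collapse = "\t")
  writeLines(header, con)
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], "na", .fmtNum(mat[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname readGct
#' @export
readExpression <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.2")) return(readGct(path))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
  if (anyDuplicated(tab[[1]]))
    stop("duplicate feature id: ", tab[[1]][duplicated(tab[[1]])][1])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  storage.mode(mat) <- "double"
  .checkExprMatrix(mat)
}

#' Read / write two-class CLS phenotype labels
#'
#' Standard three-line CLS dialect: counts line (\code{n k 1}), class-name
#' line (\code{# name0 name1}), label line. Labels may be 0/1 or the class
#' names; exactly two classes are required. Sample names are not part of
#' the format, so labels are returned unnamed, aligned with the expression
#' matrix columns.
#'
#' @param path file path.
#' @return Integer vector of 0/1 labels.
#' @export
readCls <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("CLS file needs 3 lines")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_classes <- as.integer(hdr[2])
  if (!is.na(n_classes) && n_classes != 2L)
    stop("CLS declares ", n_classes, " classes; exactly 2 required")
  cls_names <- strsplit(trimws(sub("^#\\s*", "", lines[2])), "\\s+")[[1]]
  toks <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(hdr) >= 1L && !is.na(as.integer(hdr[1])) &&
      length(toks) != as.integer(hdr[1]))
    stop("CLS label count differs from declared sample count")
  if (all(toks %in% c("0", "1"))) {
    labels <- as.integer(toks)
  } else if (all(toks %in% cls_names) && length(cls_names) == 2L) {
    labels <- as.integer(match(toks, cls_names) - 1L)
  } else {
    stop("CLS labels must be 0/1 or the two declared class names")
  }
  if (length(unique(labels)) != 2L)
    stop("CLS must contain both classes")
  labels
}

#' @rdname readCls
#' @param labels 0/1 vector (names ignored).
#' @param class_names two class display names.
#' @export
writeCls <- function(labels, path, class_names = c("class0", "class1")) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1))
  writeLines(c(paste(length(labels), 2, 1),
               paste("#", class_names[1], class_names[2]),
               paste(labels, collapse = " ")), path)
  invisible(path)
}

#' Write / read a reannotation map
#'
#' TSV with columns \code{gene_id}, \code{gene_name}, \code{n_probes},
#' \code{probe_ids} (comma-joined), plus a JSON provenance sidecar
#' (\code{<path>.provenance.json}) carrying the parameters and per-stage
#' filter counters.
#'
#' @param map a \linkS4class{ReannotationMap}.
#' @param path output TSV path.
#' @return Invisibly (write) the path; (read) the map.
#' @export
writeReannotationMap <- function(map, path) {
  stopifnot(is(map, "ReannotationMap"))
  g <- names(map@geneToProbes)
  gn <- map@geneNames[g]
  gn[is.na(gn)] <- g[is.na(gn)]
  if (length(g) == 0L) gn <- character(0)
  tab <- data.frame(gene_id = g, gene_name = unname(gn),
                    n_probes = unname(lengths(map@geneToProbes)),
                    probe_ids = vapply(map@geneToProbes, .joinIds, ""),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(params = map@params,
                            provenance = map@provenance),
                       paste0(path, ".provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeReannotationMap
#' @export
readReannotationMap <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".provenance.json")
  params <- reannotationParams()
  prov <- list()
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    params <- utils::modifyList(params, js$params)
    prov <- as.list(js$provenance)
  }
  g2p <- lapply(tab$probe_ids, .splitIds)
  names(g2p) <- tab$gene_id
  gn <- setNames(tab$gene_name, tab$gene_id)
  new("ReannotationMap", geneToProbes = g2p, geneNames = gn,
      params = params, provenance = prov)
}

#' Read / write the instance metadata table
#'
#' TSV with columns \code{instance_id}, \code{drug_name},
#' \code{treatment_samples}, \code{control_samples} (comma-joined ids).
#'
#' @param path file path.
#' @return data.frame (read) or invisibly the path (write).
#' @export
readInstances <- function(path) {
  .parseInstanceTable(read.delim(path, stringsAsFactors = FALSE,
                                 comment.char = "#"))
}

#' @rdname readInstances
#' @param instances data.frame to write.
#' @export
writeInstances <- function(instances, path) {
  write.table(.parseInstanceTable(instances), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# stamped TSV writer shared by the CLI result writers
.writeResultTsv <- function(tab, path, config = list(), seed = NULL,
                            num_cols = character(0)) {
  for (cn in num_cols) tab[[cn]] <- .fmtNum(tab[[cn]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lncSigMatch %s",
                     as.character(packageVersion("lncSigMatch"))), con)
  writeLines(sprintf("# config_hash: %s",
                     .hash32(paste(deparse(config), collapse = ""))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  if (nrow(tab) > 0L)
    writeLines(do.call(paste, c(unname(as.list(tab)), sep = "\t")), con)
  invisible(path)
}

#' Write ORA / LSEA result tables
#'
#' Deterministic TSVs with header comment lines recording the package
#' version, a config hash, and the seed. Columns mirror the analysis
#' result tables: for ORA \code{drug, m, t, n, r, overlap_members,
#' p_value, q_value}; for LSEA \code{drug, size, es, nes, p_nominal,
#' q_fdr, p_fwer, leading_edge}.
#'
#' @param res result data.frame from \code{\link{oraEnrich}} /
#'   \code{\link{lsea}}.
#' @param path output path.
#' @param config optional configuration list folded into the hash.
#' @param seed optional seed to record.
#' @return Invisibly, the path.
#' @export
writeOraResults <- function(res, path, config = list(), seed = NULL) {
  cols <- c("drug", "m", "t", "n", "r", "overlap_members", "p_value",
            "q_value")
  .writeResultTsv(res[, cols], path, config, seed,
                  num_cols = c("p_value", "q_value"))
}

#' @rdname writeOraResults
#' @export
writeLseaResults <- function(res, path, config = list(), seed = NULL) {
  cols <- c("drug", "size", "es", "nes", "p_nominal", "q_fdr", "p_fwer",
            "leading_edge")
  .writeResultTsv(res[, cols], path, config, seed,
                  num_cols = c("es", "nes", "p_nominal", "q_fdr", "p_fwer"))
}
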