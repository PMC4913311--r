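# Template databanks: build hybrid-profile records from structures (optionally
# grouped into families with a structural alignment), serialize them, search
# them with a query profile, and render annotated alignments.

#' Build a template databank from structure families
#'
#' For each family, Protein Blocks and solvent-accessibility classes are
#' computed per member from its coordinates, mapped onto the family
#' alignment, and turned into frequency profiles on the master member's
#' columns; the amino-acid profile comes from the family alignment
#' (single-member families give one-hot columns plus pseudocounts).
#'
#' @param families list of family specs, each a list with elements
#'   \code{id}, \code{description} (optional), \code{members} (list of
#'   [structure_chain()]), \code{alignment} (character vector of aligned
#'   member sequences; optional for single-member families), \code{master}
#'   (1-based master member, default 1).
#' @param beta,eps AA pseudocount weight and PB/SA smoothing (see
#'   [build_aa_profile()]).
#' @param sasa_points quadrature points for [residue_sasa()].
#' @return object of class \code{template_databank}: list of records, each
#'   with \code{id}, \code{description}, \code{profile}, \code{sequence},
#'   \code{pb}, \code{sa}, \code{length}.
#' @export
build_databank <- function(families, beta = 10, eps = 0.05,
                           sasa_points = 960) {
  records <- list()
  for (fam in families) {
    rec <- tryCatch(
      .build_family_record(fam, beta = beta, eps = eps,
                           sasa_points = sasa_points),
      error = function(e) {
        if (grepl("alignment", conditionMessage(e))) stop(e)
        warning("skipping family '", fam$id %||% "?", "': ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(rec)) records[[rec$id]] <- rec
  }
  if (!length(records)) stop("no readable families: empty databank")
  structure(list(records = records), class = "template_databank")
}

.build_family_record <- function(fam, beta, eps, sasa_points) {
  members <- fam$members
  if (!length(members)) stop("family has no members")
  master <- fam$master %||% 1L
  aln <- fam$alignment
  if (is.null(aln)) {
    if (length(members) > 1)
      stop("multi-member family '", fam$id, "' needs an alignment")
    aln <- chain_sequence(members[[1]])
  }
  aln <- toupper(aln)
  if (length(aln) != length(members))
    stop("alignment rows (", length(aln), ") != members (", length(members),
         ") in family '", fam$id, "'")
  # per-member structural states mapped onto alignment columns
  aligned_pb <- character(length(members))
  aligned_sa <- vector("list", length(members))
  for (k in seq_along(members)) {
    ch <- members[[k]]
    degap <- gsub("[-.]", "", aln[k])
    if (degap != chain_sequence(ch))
      stop("alignment/sequence mismatch for member ", k, " ('",
           ch$id, "') of family '", fam$id, "'")
    pb <- strsplit(chain_pb(ch), "")[[1]]
    sa <- chain_sa_class(ch, n_points = sasa_points)
    cols <- strsplit(aln[k], "")[[1]]
    pbrow <- rep("-", length(cols))
    sarow <- rep(NA_integer_, length(cols))
    idx <- which(!cols %in% c("-", "."))
    pbrow[idx] <- pb
    sarow[idx] <- sa
    aligned_pb[k] <- paste(pbrow, collapse = "")
    aligned_sa[[k]] <- sarow
  }
  aap <- build_aa_profile(aln, master_index = master, beta = beta)
  pbp <- build_pb_profile_from_structures(aligned_pb, master_index = master,
                                          eps = eps)
  sap <- build_sa_profile_from_structures(aligned_sa, master_index = master,
                                          eps = eps)
  prof <- concat_hybrid(aap, pbp, sap, id = fam$id,
                        description = fam$description %||% "")
  mseq <- chain_sequence(members[[master]])
  mcols <- which(strsplit(aln[master], "")[[1]] != "-")
  mpb <- strsplit(aligned_pb[master], "")[[1]][mcols]
  msa_cls <- aligned_sa[[master]][mcols]
  list(id = fam$id, description = fam$description %||% "",
       profile = prof, sequence = mseq,
       pb = paste(mpb, collapse = ""), sa = msa_cls, length = length(prof))
}

#' @export
print.template_databank <- function(x, ...) {
  cat("template_databank:", length(x$records), "records\n")
  invisible(x)
}

#' Write a databank to a directory
#'
#' Records are concatenated into \code{templates.orp} (versioned text
#' records) next to \code{index.tsv} (id, offset, length, description);
#' both files are plain text and inspectable.
#'
#' @param db a \code{template_databank}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_databank <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_lines <- character(0)
  idx <- data.frame(id = character(0), offset = integer(0),
                    n_lines = integer(0), length = integer(0),
                    description = character(0))
  for (rec in db$records) {
    lines <- .orp_record_lines(rec$profile, pb_string = rec$pb,
                               sa_classes = rec$sa)
    idx <- rbind(idx, data.frame(
      id = rec$id, offset = length(all_lines) + 1L,
      n_lines = length(lines), length = rec$length,
      description = rec$description))
    all_lines <- c(all_lines, lines)
  }
  writeLines(all_lines, file.path(dir, "templates.orp"))
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a databank written by [write_databank()]
#'
#' @param dir databank directory.
#' @return a \code{template_databank}.
#' @export
read_databank <- function(dir) {
  idx <- utils::read.table(file.path(dir, "index.tsv"), sep = "\t",
                           header = TRUE, colClasses = c(
                             "character", "integer", "integer", "integer",
                             "character"))
  lines <- readLines(file.path(dir, "templates.orp"))
  records <- list()
  for (k in seq_len(nrow(idx))) {
    span <- seq(idx$offset[k], length.out = idx$n_lines[k])
    prof <- .orp_parse_record(lines[span], offset = idx$offset[k] - 1L)
    records[[idx$id[k]]] <- list(
      id = prof$id, description = prof$description, profile = prof,
      sequence = prof$sequence, pb = attr(prof, "pb_string"),
      sa = attr(prof, "sa_classes"), length = length(prof))
  }
  structure(list(records = records), class = "template_databank")
}

#' Search a databank with a query hybrid profile
#'
#' Aligns the query against every template record in the chosen mode and
#' returns the top hits ranked by total score (raw alignment score plus the
#' weighted correlation score); ties break by template id.
#'
#' @param query a \code{hybrid_profile}.
#' @param db a \code{template_databank}.
#' @param params a [scoring_params()].
#' @param max_hits maximum number of hits returned (default 100).
#' @param mode overrides \code{params$mode}.
#' @return object of class \code{databank_search}: \code{hits} (data.frame
#'   with rank, id, description, score, template_length, q_start, q_end,
#'   t_start, t_end, coverage, identity) and \code{alignments} (named list
#'   of \code{profile_alignment}s for the returned hits).
#' @export
search_databank <- function(query, db, params = scoring_params(),
                            max_hits = 100, mode = NULL) {
  if (!length(db$records)) stop("empty databank")
  if (max_hits < 1) stop("max_hits must be >= 1")
  L <- length(query)
  if (L < 15 || L > 1000)
    warning("query length ", L, " outside the supported 15-1000 range")
  alns <- lapply(db$records, function(rec)
    align_profiles(query, rec$profile, params, mode = mode))
  ids <- names(db$records)
  hits <- data.frame(
    id = ids,
    description = vapply(db$records, function(r) r$description, character(1)),
    score = vapply(alns, function(a) a$total, numeric(1)),
    template_length = vapply(db$records, function(r) r$length, integer(1)),
    q_start = vapply(alns, function(a) a$bounds[["q_start"]], numeric(1)),
    q_end = vapply(alns, function(a) a$bounds[["q_end"]], numeric(1)),
    t_start = vapply(alns, function(a) a$bounds[["t_start"]], numeric(1)),
    t_end = vapply(alns, function(a) a$bounds[["t_end"]], numeric(1)),
    coverage = vapply(alns, function(a) a$coverage, numeric(1)),
    identity = vapply(alns, function(a) a$identity, numeric(1)),
    row.names = NULL)
  ord <- order(-hits$score, hits$id)
  hits <- hits[ord, , drop = FALSE][seq_len(min(max_hits, nrow(hits))), ,
                                    drop = FALSE]
  hits <- cbind(rank = seq_len(nrow(hits)), hits)
  rownames(hits) <- NULL
  structure(list(hits = hits, alignments = alns[hits$id], query = query),
            class = "databank_search")
}

#' @export
print.databank_search <- function(x, ...) {
  cat("databank_search:", nrow(x$hits), "hits\n")
  print(utils::head(x$hits, 10))
  invisible(x)
}

#' Render one hit as an annotated text alignment
#'
#' Blocks of 60 columns with tracks: query secondary structure (from the
#' query's PB annotation when available), query PB, query sequence with
#' 1-based numbering, a match line (\code{|} identity, \code{+} positive
#' column score), template sequence, template PB, and template secondary
#' structure mapped from its PB letters.
#'
#' @param search a \code{databank_search}.
#' @param id template id (default: the rank-1 hit).
#' @param db the searched \code{template_databank} (for template tracks).
#' @param query_pb optional query PB string annotation.
#' @param width columns per block (default 60).
#' @return character vector of text lines.
#' @export
render_alignment <- function(search, db, id = NULL, query_pb = NULL,
                             width = 60) {
  id <- id %||% search$hits$id[1]
  aln <- search$alignments[[id]]
  rec <- db$records[[id]]
  if (is.null(aln) || is.null(rec)) stop("no such hit: ", id)
  qseq <- strsplit(search$query$sequence, "")[[1]]
  tseq <- strsplit(rec$sequence, "")[[1]]
  tpb <- strsplit(rec$pb %||% strrep("Z", rec$length), "")[[1]]
  qpb <- if (!is.null(query_pb)) strsplit(query_pb, "")[[1]]
  cols <- aln$columns
  n <- nrow(cols)
  qs <- ifelse(is.na(cols$q), "-", qseq[cols$q])
  ts <- ifelse(is.na(cols$t), "-", tseq[cols$t])
  qb <- if (is.null(qpb)) rep("-", n) else ifelse(is.na(cols$q), "-", qpb[cols$q])
  tb <- ifelse(is.na(cols$t), "-", tpb[cols$t])
  match_line <- ifelse(!is.na(cols$q) & !is.na(cols$t) & qs == ts, "|",
                       ifelse(aln$s_l > 0, "+", " "))
  out <- c(sprintf("# %s vs %s  total=%.2f identity=%.1f%% coverage=%.1f%%",
                   search$query$id, id, aln$total, aln$identity,
                   aln$coverage))
  for (start in seq(1, n, by = width)) {
    sel <- start:min(start + width - 1, n)
    qnum <- cols$q[sel]; tnum <- cols$t[sel]
    q1 <- qnum[!is.na(qnum)]; t1 <- tnum[!is.na(tnum)]
    rng <- function(v, f) if (length(v)) as.character(f(v)) else ""
    lab <- function(tag, s, lo = "", hi = "")
      sprintf("%-8s %5s %s %s", tag, lo, s, hi)
    out <- c(out, "",
      lab("q_ss", pb_to_ss(paste(qb[sel], collapse = ""))),
      lab("q_pb", paste(qb[sel], collapse = "")),
      lab("query", paste(qs[sel], collapse = ""), rng(q1, min), rng(q1, max)),
      lab("match", paste(match_line[sel], collapse = "")),
      lab("template", paste(ts[sel], collapse = ""), rng(t1, min), rng(t1, max)),
      lab("t_pb", paste(tb[sel], collapse = "")),
      lab("t_ss", pb_to_ss(paste(tb[sel], collapse = ""))))
  }
  out
}

#' Write a hit table to TSV or JSON
#'
#' One row per hit with the ranked-hit fields (rank, id, description, score,
#' template length, aligned bounds, coverage, identity) in stable column
#' order; zero hits give a header-only TSV or an empty JSON array.
#'
#' @param hits the \code{hits} data.frame of a [search_databank()] result
#'   (or the result object itself).
#' @param path output file.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_hit_table <- function(hits, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(hits, "databank_search")) hits <- hits$hits
  if (format == "tsv") {
    utils::write.table(hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(hits, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
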