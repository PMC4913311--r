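# Text serialization of hybrid profiles (.orp): a versioned, tab-delimited,
# inspectable format with fixed column order 20 AA, gap, 16 PB, 10 SA.

.ORP_VERSION <- 1L
.ORP_DIGITS <- 6L

.orp_colnames <- function() {
  c(aa_alphabet(), "gap", paste0("pb_", pb_alphabet()),
    paste0("sa_", 1:10))
}

# class 1..10 encoded as digits 0..9 in the #SA header line
.sa_encode <- function(cls) {
  paste(ifelse(is.na(cls), "-", as.character(cls - 1L)), collapse = "")
}
.sa_decode <- function(s) {
  ch <- strsplit(s, "")[[1]]
  ifelse(ch == "-", NA_integer_, as.integer(ch) + 1L)
}

# format a hybrid profile (plus optional PB/SA state annotation) as .orp lines
.orp_record_lines <- function(p, pb_string = NULL, sa_classes = NULL) {
  L <- length(p)
  num <- cbind(p$aa, p$gap, p$pb, p$sa)
  body <- vapply(seq_len(L), function(i)
    paste(c(i, substr(p$sequence, i, i),
            formatC(num[i, ], format = "f", digits = .ORP_DIGITS)),
          collapse = "\t"), character(1))
  c(paste0("#ORP ", .ORP_VERSION),
    paste0("#ID ", p$id),
    paste0("#DESC ", p$description),
    paste0("#SEQ ", p$sequence),
    if (!is.null(pb_string)) paste0("#PB ", pb_string),
    if (!is.null(sa_classes)) paste0("#SA ", .sa_encode(sa_classes)),
    paste0("#COLUMNS pos res ", paste(.orp_colnames(), collapse = " ")),
    body,
    "#END")
}

.orp_parse_record <- function(lines, offset = 0) {
  hdr <- function(tag) {
    hit <- grep(paste0("^#", tag, "( |$)"), lines)
    if (!length(hit)) return(NULL)
    sub(paste0("^#", tag, " ?"), "", lines[hit[1]])
  }
  ver <- hdr("ORP")
  if (is.null(ver) || !identical(as.integer(ver), .ORP_VERSION))
    stop("unsupported version: '", ver %||% "missing", "'")
  body_idx <- which(!startsWith(lines, "#"))
  n_expect <- 2 + length(.orp_colnames())
  num <- matrix(0, length(body_idx), length(.orp_colnames()),
                dimnames = list(NULL, .orp_colnames()))
  for (k in seq_along(body_idx)) {
    f <- strsplit(lines[body_idx[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) != n_expect)
      stop("wrong column count (", length(f), " of ", n_expect,
           ") at line ", offset + body_idx[k])
    num[k, ] <- as.numeric(f[-(1:2)])
  }
  seq <- hdr("SEQ")
  p <- structure(list(
    id = hdr("ID") %||% "profile",
    description = hdr("DESC") %||% "",
    sequence = seq,
    aa = num[, aa_alphabet(), drop = FALSE],
    gap = unname(num[, "gap"]),
    pb = `colnames<-`(num[, paste0("pb_", pb_alphabet()), drop = FALSE],
                      pb_alphabet()),
    sa = `colnames<-`(num[, paste0("sa_", 1:10), drop = FALSE],
                      as.character(1:10))), class = "hybrid_profile")
  pb_s <- hdr("PB"); sa_s <- hdr("SA")
  attr(p, "pb_string") <- pb_s
  attr(p, "sa_classes") <- if (!is.null(sa_s)) .sa_decode(sa_s)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a hybrid profile to a .orp file
#'
#' @param profile a \code{hybrid_profile}.
#' @param path output file.
#' @param pb_string,sa_classes optional per-residue state annotation stored
#'   in the record header (kept by template records).
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path, pb_string = NULL,
                          sa_classes = NULL) {
  writeLines(.orp_record_lines(profile, pb_string, sa_classes), path)
  invisible(path)
}

#' Read a hybrid profile from a .orp file
#'
#' @param path file written by [write_profile()].
#' @return a \code{hybrid_profile}; PB/SA state annotations, if present, are
#'   attached as attributes \code{pb_string} and \code{sa_classes}.
#' @export
read_profile <- function(path) {
  .orp_parse_record(readLines(path))
}
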