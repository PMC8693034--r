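#' Template hit tables
#'
#' Template hits are carried as a tibble with one row per hit and the
#' columns `template_id`, `probability` (percent, 0-100), `evalue`, and
#' `alignment`, a list-column of tibbles with `query_pos`,
#' `template_pos` (both 1-based, strictly increasing: local gapped
#' alignments) and `confidence` (per-position alignment confidence
#' s_k(i) in \[0,1\]).
#'
#' The on-disk dialect is a plain tab-separated format of our own (the
#' native HHsearch `.hhr` layout is irregular and parsing it is a
#' non-goal): per hit, one header line `H <id> <probability> <evalue>`
#' followed by one `A <query_pos> <template_pos> <confidence>` line per
#' aligned pair.  Lines starting with `#` are comments.
#'
#' @param template_id,probability,evalue Scalar hit descriptors.
#' @param query_pos,template_pos,confidence Aligned-pair vectors.
#' @return A one-row hits tibble.
#' @export
new_template_hit <- function(template_id, probability, evalue,
                             query_pos, template_pos, confidence) {
  if (probability < 0 || probability > 100) {
    stop_protgeom("hit probability must be a percentage in [0,100]")
  }
  if (evalue < 0) stop_protgeom("hit E-value must be nonnegative")
  if (is.unsorted(query_pos, strictly = TRUE) ||
      is.unsorted(template_pos, strictly = TRUE)) {
    stop_protgeom(
      "aligned pairs must be strictly increasing in both coordinates"
    )
  }
  if (any(confidence > 1 | confidence < 0)) {
    warning("confidence values outside [0,1] clipped", call. = FALSE)
    confidence <- pmin(1, pmax(0, confidence))
  }
  tibble::tibble(
    template_id = template_id,
    probability = probability,
    evalue = evalue,
    alignment = list(tibble::tibble(
      query_pos = as.integer(query_pos),
      template_pos = as.integer(template_pos),
      confidence = as.numeric(confidence)
    ))
  )
}

empty_hits <- function() {
  tibble::tibble(
    template_id = character(), probability = numeric(),
    evalue = numeric(), alignment = list()
  )
}

#' Read a template hit table
#'
#' @param path Path to a hit table in the dialect described in
#'   [new_template_hit()].
#' @return A hits tibble in file order; zero rows for an empty table
#'   (the pipeline then runs in FM-only mode).
#' @export
read_hits_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t")
  tag <- vapply(fields, `[`, character(1), 1)
  if (!all(tag %in% c("H", "A"))) {
    stop_protgeom("unrecognised line tag in hit table: ", setdiff(tag, c("H", "A"))[1])
  }
  if (tag[1] != "H") stop_protgeom("hit table must start with an H line")
  starts <- which(tag == "H")
  ends <- c(starts[-1] - 1L, length(lines))
  hits <- purrr::map2(starts, ends, function(s, e) {
    h <- fields[[s]]
    if (length(h) != 4L) stop_protgeom("malformed H line: ", lines[s])
    al <- fields[seq(s + 1L, length.out = e - s)]
    if (length(al) == 0L) stop_protgeom("hit '", h[2], "' has no aligned pairs")
    ok <- vapply(al, length, integer(1)) == 4L
    if (!all(ok)) stop_protgeom("malformed A line under hit '", h[2], "'")
    am <- do.call(rbind, lapply(al, function(f) as.numeric(f[2:4])))
    new_template_hit(
      template_id = h[2],
      probability = as.numeric(h[3]),
      evalue = as.numeric(h[4]),
      query_pos = am[, 1], template_pos = am[, 2], confidence = am[, 3]
    )
  })
  dplyr::bind_rows(hits)
}

#' Write a template hit table
#'
#' @param hits A hits tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# protgeom template hits v1", con)
  for (r in seq_len(nrow(hits))) {
    writeLines(sprintf(
      "H\t%s\t%.6g\t%.6g",
      hits$template_id[r], hits$probability[r], hits$evalue[r]
    ), con)
    al <- hits$alignment[[r]]
    writeLines(sprintf(
      "A\t%d\t%d\t%.6g", al$query_pos, al$template_pos, al$confidence
    ), con)
  }
  invisible(path)
}

#' Keep good templates and truncate to the top N
#'
#' A template is *good* if its probability exceeds 60% or its E-value is
#' below 0.001.  Hits are assumed to arrive in search-rank order; after
#' filtering, at most `n_max` are kept (the pipeline feeds the top
#' N <= 10 templates to the attention module).  Zero surviving hits
#' signal FM-only mode.
#'
#' @param hits A hits tibble.
#' @param n_max Maximum number of templates to retain.
#' @param min_probability,max_evalue The good-template thresholds.
#' @return The filtered hits tibble, original order preserved.
#' @export
filter_and_rank_templates <- function(hits, n_max = 10,
                                      min_probability = 60,
                                      max_evalue = 0.001) {
  if (nrow(hits) == 0L) return(hits)
  good <- hits$probability > min_probability | hits$evalue < max_evalue
  head(hits[good, , drop = FALSE], n_max)
}
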