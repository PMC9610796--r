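#' Write an annotation to GFF3
#'
#' Emits ORFs as `gene` features and hrs as `repeat_region` parents with
#' `repeat_unit` children, 1-based inclusive coordinates. ORFs spanning the
#' circular junction (stored with `end > genome length`) are split losslessly
#' into two segments sharing an ID; [read_gff3()] re-joins them.
#'
#' @param genome The [genome()] being annotated.
#' @param orfs ORF tibble (may be `NULL`).
#' @param hrs hr tibble from [classify_hrs()] (may be `NULL`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, orfs, hrs, path) {
  len <- genome_length(genome)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, len))
  esc <- function(x) gsub("[;=,\t]", "_", x)
  feat <- function(start, end, type, strand, attrs) {
    sprintf("%s\tnpvanno\t%s\t%d\t%d\t.\t%s\t.\t%s",
            genome$id, type, start, end, strand, attrs)
  }
  if (!is.null(orfs) && nrow(orfs) > 0L) {
    for (i in seq_len(nrow(orfs))) {
      o <- orfs[i, ]
      if (o$start < 1L || o$start > len || o$end < o$start ||
          (o$end > len && !genome$circular) || (o$end - o$start + 1L) > len) {
        abort_npv("ORF coordinates outside genome", "bad_coordinates")
      }
      id <- if (is.na(o$orf_id)) paste0("orf_at_", o$start) else paste0("orf", o$orf_id)
      attrs <- sprintf(
        "ID=%s;Name=%s;aa_length=%d;annotation_basis=%s",
        id, esc(ifelse(is.na(o$name), id, o$name)), o$aa_length,
        ifelse(is.na(o$annotation_basis), "unassigned", o$annotation_basis)
      )
      if (o$end > len) { # wrapped: split into two segments, same ID
        lines <- c(
          lines,
          feat(o$start, len, "gene", o$strand, paste0(attrs, ";part=1")),
          feat(1L, o$end - len, "gene", o$strand, paste0(attrs, ";part=2"))
        )
      } else {
        lines <- c(lines, feat(o$start, o$end, "gene", o$strand, attrs))
      }
    }
  }
  if (!is.null(hrs) && nrow(hrs) > 0L) {
    for (i in seq_len(nrow(hrs))) {
      h <- hrs[i, ]
      if (h$region_start < 1L || h$region_start > len) {
        abort_npv("hr coordinates outside genome", "bad_coordinates")
      }
      lines <- c(lines, feat(
        h$region_start, min(h$region_end, if (genome$circular) h$region_end else len),
        "repeat_region", "+",
        sprintf("ID=%s;n_units=%d;consensus=%s", h$hr_id, h$n_units, h$consensus)
      ))
      u <- h$units[[1]]
      for (j in seq_len(nrow(u))) {
        lines <- c(lines, feat(
          u$start[j], u$end[j], "repeat_unit",
          ifelse(u$orientation[j] == "reverse", "-", "+"),
          sprintf("ID=%s.unit%d;Parent=%s", h$hr_id, j, h$hr_id)
        ))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 annotation written by [write_gff3()]
#'
#' @param path Path to the GFF3 file.
#' @return A list with `orfs` (tibble) and `hrs` (tibble with `units`
#'   list-column); wrapped ORF segments are re-joined.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) {
    abort_npv(paste0("input not found: ", path), "input_not_found")
  }
  raw <- readLines(path)
  seq_len_line <- grep("^##sequence-region", raw, value = TRUE)
  glen <- if (length(seq_len_line)) {
    as.integer(utils::tail(strsplit(seq_len_line[1], " ")[[1]], 1))
  } else NA_integer_
  rows <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(rows) == 0L) {
    return(list(orfs = find_orfs(genome("x", "ATGTAA"), 1)[0, ],
                hrs = classify_hrs(tibble::tibble())[0, ]))
  }
  f <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]*"), attrs))
    ifelse(lengths(regmatches(attrs, gregexpr(paste0(key, "=[^;]*"), attrs))) > 0,
           sub(paste0(key, "="), "", m), NA_character_)
  }
  df <- tibble::tibble(
    type = f[, 3], start = as.integer(f[, 4]), end = as.integer(f[, 5]),
    strand = f[, 7], attrs = f[, 9]
  )
  genes <- dplyr::filter(df, .data$type == "gene")
  orfs <- NULL
  if (nrow(genes) > 0L) {
    genes$id <- vapply(genes$attrs, attr_get, character(1), key = "ID")
    genes$part <- vapply(genes$attrs, attr_get, character(1), key = "part")
    joined <- genes |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(
        start = .data$start[is.na(.data$part) | .data$part == "1"][1],
        end = if (dplyr::n() == 1L) .data$end[1] else {
          .data$end[.data$part == "2"][1] + glen
        },
        strand = .data$strand[1],
        name = attr_get(.data$attrs[1], "Name"),
        basis = attr_get(.data$attrs[1], "annotation_basis"),
        .groups = "drop"
      )
    orfs <- purrr::map_dfr(seq_len(nrow(joined)), function(i) {
      orf_record(
        joined$start[i], joined$end[i], joined$strand[i],
        orf_id = suppressWarnings(as.integer(sub("^orf", "", joined$id[i]))),
        name = joined$name[i],
        annotation_basis = ifelse(joined$basis[i] == "unassigned",
                                  NA_character_, joined$basis[i])
      )
    })
    orfs <- dplyr::arrange(orfs, .data$start)
  }
  regions <- dplyr::filter(df, .data$type == "repeat_region")
  units <- dplyr::filter(df, .data$type == "repeat_unit")
  hrs <- NULL
  if (nrow(regions) > 0L) {
    hrs <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      id <- attr_get(r$attrs, "ID")
      uu <- units[vapply(units$attrs, function(a) {
        identical(attr_get(a, "Parent"), id)
      }, logical(1)), ]
      tibble::tibble(
        hr_id = id, region_start = r$start, region_end = r$end,
        n_units = as.integer(attr_get(r$attrs, "n_units")),
        consensus = attr_get(r$attrs, "consensus"),
        units = list(tibble::tibble(
          start = uu$start, end = uu$end,
          orientation = ifelse(uu$strand == "-", "reverse", "forward")
        ))
      )
    })
  }
  list(orfs = orfs, hrs = hrs)
}
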