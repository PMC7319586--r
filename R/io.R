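# File formats: band-table CSV, saturation/Hill TSV, model config JSON/YAML,
# promoter FASTA, IR hits TSV/BED6, kinetic reads CSV, result JSON.

#' Read a quantified EMSA band table from CSV
#'
#' Expected header: `lane,replicate,conc,conc_unit,band_0,band_1,...`.
#' Concentrations are converted to uM at parse time according to the per-row
#' `conc_unit` column (M, mM, uM, nM, pM).
#'
#' @param path CSV path.
#' @return a [band_table()].
#' @export
read_band_table <- function(path) {
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) cf_stop(
                  paste0("cannot parse band table ", path, ": ",
                         conditionMessage(e)), "coopfit_parse_error"))
  need <- c("lane", "replicate", "conc", "conc_unit")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    cf_stop(paste0("band table ", path, " lacks column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "coopfit_parse_error")
  }
  bands <- grep("^band_", names(d), value = TRUE)
  if (length(bands) < 2L) {
    cf_stop("band table needs at least columns band_0 and band_1",
            "coopfit_parse_error")
  }
  conc <- convert_to_uM(d$conc, d$conc_unit)
  band_table(conc, as.matrix(d[bands]), replicate = d$replicate)
}

#' Write a band table to CSV
#'
#' @param table a [band_table()].
#' @param path destination CSV.
#' @param conc_unit unit to declare in the file (values are stored in that
#'   unit; default uM, i.e. values unchanged).
#' @export
write_band_table <- function(table, path, conc_unit = "uM") {
  d <- as.data.frame(table)
  d$conc <- d$conc / .conc_unit_factors[[conc_unit]]
  d$conc_unit <- conc_unit
  d <- d[c("lane", "replicate", "conc", "conc_unit", .band_cols(d))]
  write_atomically(path, function(p) {
    utils::write.csv(d, p, row.names = FALSE, quote = FALSE)
  })
}

#' Write / read a saturation curve as TSV
#'
#' @param curve a [saturation_curve()].
#' @param path destination TSV.
#' @export
write_saturation_tsv <- function(curve, path) {
  write_atomically(path, function(p) {
    utils::write.table(as.data.frame(curve), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  })
}

#' @rdname write_saturation_tsv
#' @export
read_saturation_tsv <- function(path) {
  d <- utils::read.delim(path)
  saturation_curve(d$concentration, d$Y, d$sem, d$n_replicates)
}

#' Write Hill points as TSV
#'
#' @param points a `hill_points` data.frame.
#' @param path destination TSV.
#' @export
write_hill_points_tsv <- function(points, path) {
  write_atomically(path, function(p) {
    utils::write.table(as.data.frame(points), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  })
}

#' Write an analysis result (list or hill_result) as JSON
#'
#' @param x a `hill_result`, `fit_result` or plain list.
#' @param path destination JSON.
#' @export
write_result_json <- function(x, path) {
  write_atomically(path, function(p) {
    jsonlite::write_json(unclass(x), p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  })
}

#' Read / write a binding-model configuration (JSON or YAML)
#'
#' Config schema: `sites:` list of `{id, kd_uM}` records, optional
#' `coupling:` list of `{i, j, omega}` records. Unknown top-level keys are
#' rejected.
#'
#' @param path config path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return a [promoter_model()].
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  unknown <- setdiff(names(cfg), c("sites", "coupling"))
  if (length(unknown)) {
    cf_stop(paste0("unknown model config key(s): ",
                   paste(unknown, collapse = ", ")), "coopfit_parse_error")
  }
  cf_assert(length(cfg$sites) >= 1L, "model config needs at least one site",
            "coopfit_parse_error")
  kds <- vapply(cfg$sites, function(s) as.numeric(s$kd_uM), numeric(1))
  names(kds) <- vapply(cfg$sites, function(s) as.character(s$id), character(1))
  promoter_model(kds, coupling = cfg$coupling)
}

#' @rdname read_model_config
#' @param model a [promoter_model()] to serialise.
#' @export
write_model_config <- function(model, path) {
  .check_model(model)
  sites <- lapply(seq_along(model$kds), function(i) {
    list(id = model$site_ids[i], kd_uM = unname(model$kds[i]))
  })
  coupling <- list()
  n <- length(model$kds)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (model$omega[i, j] != 1) {
        coupling[[length(coupling) + 1L]] <-
          list(i = model$site_ids[i], j = model$site_ids[j],
               omega = unname(model$omega[i, j]))
      }
    }
  }
  cfg <- list(sites = sites)
  if (length(coupling)) cfg$coupling <- coupling
  write_atomically(path, function(p) {
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::write_yaml(cfg, p)
    } else {
      jsonlite::write_json(cfg, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
  })
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @param anchor optional anchor position applied to every sequence (default:
#'   sequence length + 1, i.e. the start codon immediately follows).
#' @return list of [promoter_sequence()] objects, named by FASTA id.
#' @export
read_promoter_fasta <- function(path, anchor = NULL) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) cf_stop(
                    paste0("cannot parse FASTA ", path, ": ",
                           conditionMessage(e)), "coopfit_parse_error"))
  out <- lapply(seq_along(set), function(i) {
    promoter_sequence(as.character(set[[i]]),
                      id = sub("\\s.*$", "", names(set)[i]), anchor = anchor)
  })
  names(out) <- vapply(out, function(s) s$id, character(1))
  out
}

#' Write a promoter sequence to FASTA
#'
#' @param seqs a [promoter_sequence()] or list of them.
#' @param path destination FASTA.
#' @export
write_promoter_fasta <- function(seqs, path) {
  if (inherits(seqs, "promoter_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$sequence,
                                         character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  write_atomically(path, function(p) Biostrings::writeXStringSet(set, p))
}

#' Write inverted-repeat hits as TSV or BED6
#'
#' The TSV carries one row per pair. The BED6 file carries one interval per
#' arm (0-based half-open, per the BED convention), the pair id with an
#' `_L`/`_R` suffix in the name field, the mismatch count in the score field
#' and `+`/`-` strand for the left/right arm.
#'
#' @param hits an `ir_hits` data.frame from [find_inverted_repeats()].
#' @param path destination file.
#' @export
write_ir_tsv <- function(hits, path) {
  write_atomically(path, function(p) {
    utils::write.table(as.data.frame(hits), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  })
}

#' @rdname write_ir_tsv
#' @export
write_ir_bed <- function(hits, path) {
  d <- as.data.frame(hits)
  rows <- lapply(seq_len(nrow(d)), function(r) {
    pid <- paste0("IRpair_", r)
    data.frame(
      chrom = rep(d$seq_id[r], 2),
      start = c(d$left_start[r], d$right_start[r]) - 1L,
      end = c(d$left_end[r], d$right_end[r]),
      name = paste0(pid, c("_L", "_R")),
      score = rep(d$mismatches[r], 2),
      strand = c("+", "-"))
  })
  bed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character())
  write_atomically(path, function(p) {
    utils::write.table(bed, p, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  })
}

#' @rdname write_ir_tsv
#' @export
read_ir_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(d) <- c("ir_hits", "data.frame")
  d
}

#' Read kinetic reporter reads from long-format CSV
#'
#' Expected header:
#' `well,construct,antitoxin,iptg,replicate,time_s,od420,od600_first`
#' (one row per reading; `od600_first` repeated within a well). Times are
#' converted from seconds to minutes.
#'
#' @param path CSV path.
#' @return named list of [kinetic_plate_read()] objects, one per well.
#' @export
read_kinetic_csv <- function(path) {
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) cf_stop(
                  paste0("cannot parse kinetic CSV ", path, ": ",
                         conditionMessage(e)), "coopfit_parse_error"))
  need <- c("well", "time_s", "od420", "od600_first")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    cf_stop(paste0("kinetic CSV lacks column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "coopfit_parse_error")
  }
  label_cols <- intersect(c("construct", "antitoxin", "iptg", "replicate"),
                          names(d))
  out <- lapply(split(d, d$well), function(w) {
    w <- w[order(w$time_s), , drop = FALSE]
    kinetic_plate_read(w$time_s / 60, w$od420, w$od600_first[1],
                       well_id = as.character(w$well[1]),
                       condition = as.list(w[1, label_cols, drop = FALSE]))
  })
  out
}

#' Write kinetic reads to long-format CSV
#'
#' @param reads list of [kinetic_plate_read()] objects.
#' @param path destination CSV.
#' @export
write_kinetic_csv <- function(reads, path) {
  if (inherits(reads, "kinetic_plate_read")) reads <- list(reads)
  rows <- lapply(reads, function(r) {
    cond <- r$condition
    data.frame(well = r$well_id,
               construct = if (!is.null(cond$construct)) cond$construct else "",
               antitoxin = if (!is.null(cond$antitoxin)) cond$antitoxin else "",
               iptg = if (!is.null(cond$iptg)) cond$iptg else "",
               replicate = if (!is.null(cond$replicate)) cond$replicate else 1L,
               time_s = r$times * 60, od420 = r$od420,
               od600_first = r$od600_first)
  })
  write_atomically(path, function(p) {
    utils::write.csv(do.call(rbind, rows), p, row.names = FALSE, quote = FALSE)
  })
}
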