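# CSV input/output and the four headless workflows (simulate, score,
# evaluate, compare) behind the command-line interface.

.cohort_schema <- c(id = "id", age = "age",
                    menopausal_status = "menopausal_status",
                    he4 = "he4_pmol_l", ca125 = "ca125_u_ml",
                    label = "label")

#' Read a patient cohort from CSV
#'
#' Expects a comma-separated, UTF-8, header-first file with columns
#' `id`, `age`, `menopausal_status` (`pre`/`post`/`unknown`; empty cells
#' become `unknown`), `he4_pmol_l`, `ca125_u_ml`, and optionally `label`
#' (`malignant`/`benign`). Rows failing validation (non-positive or
#' missing age/markers, unrecognized status or label) are dropped and
#' reported, never silently repaired. Parsing is locale-independent
#' (decimal point only).
#'
#' @param path Path to the CSV file.
#' @return List with `cohort` (data frame with canonical columns `id`,
#'   `age`, `menopausal_status`, `he4`, `ca125`, `label`) and `rejected`
#'   (data frame `row`, `id`, `reason`; zero rows when all parsed).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  required <- c("id", "age", "menopausal_status", "he4_pmol_l",
                "ca125_u_ml")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  age <- num(raw$age)
  he4 <- num(raw$he4_pmol_l)
  ca125 <- num(raw$ca125_u_ml)
  status <- ifelse(is.na(raw$menopausal_status) |
                     raw$menopausal_status == "",
                   "unknown", raw$menopausal_status)
  label <- if ("label" %in% names(raw)) {
    ifelse(is.na(raw$label) | raw$label == "", NA_character_, raw$label)
  } else {
    rep(NA_character_, nrow(raw))
  }

  reason <- rep(NA_character_, nrow(raw))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(age) | !is.finite(age) | age <= 0,
                "unparseable or non-positive age")
  reason <- bad(is.na(he4) | he4 <= 0 | is.na(ca125) | ca125 <= 0,
                "missing or non-positive marker")
  reason <- bad(!status %in% c("pre", "post", "unknown"),
                "unrecognized menopausal_status")
  reason <- bad(!is.na(label) & !label %in% c("malignant", "benign"),
                "unrecognized label")

  keep <- is.na(reason)
  cohort <- data.frame(id = raw$id[keep], age = age[keep],
                       menopausal_status = status[keep], he4 = he4[keep],
                       ca125 = ca125[keep], label = label[keep],
                       stringsAsFactors = FALSE)
  rejected <- data.frame(row = which(!keep), id = raw$id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  list(cohort = cohort, rejected = rejected)
}

#' Write a cohort (optionally with scores) to CSV
#'
#' Canonical in-memory columns are renamed to the file schema
#' (`he4_pmol_l`, `ca125_u_ml`); any additional columns (scores,
#' classifications) are written as-is.
#'
#' @param cohort Data frame with at least the canonical cohort columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  ren <- .cohort_schema[names(.cohort_schema) %in% names(out)]
  names(out)[match(names(ren), names(out))] <- ren
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

.config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

.log_run <- function(what, config) {
  ver <- as.character(utils::packageVersion("romaP"))
  message(sprintf("[romaP %s] %s  seed=%s  config=%s", ver, what,
                  if (is.null(config$seed)) "none" else config$seed,
                  .config_hash(config)))
}

.default_config <- function(config) {
  defaults <- list(algorithm = "both", cutoffs = roma_cutoffs(),
                   equality = "ge", seed = NULL)
  utils::modifyList(defaults, config)
}

#' Read a run configuration from a YAML key-value file
#'
#' Recognized keys mirror the arguments of the `run_*` workflows:
#' `input`, `output`, `algorithm`, `seed`, `equality`, and a `cutoffs`
#' mapping with `roma_p`, `roma_pre`, `roma_post`.
#'
#' @param path Path to the YAML (or plain `key: value`) file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  yaml::read_yaml(path)
}

#' Simulate a synthetic cohort to CSV
#'
#' Writes the standard cohort CSV plus a JSON metadata sidecar
#' (`<output>.meta.json`) recording the package version, seed and
#' configuration hash.
#'
#' @param config Named list with `output` (CSV path), `seed` (mandatory
#'   for a reproducible cohort) and optionally the [cohort_spec()]
#'   scalars `n_malignant`, `n_benign`, `he4_age_drift`.
#' @return The generated cohort, invisibly.
#' @export
run_simulate <- function(config) {
  config <- .default_config(config)
  if (is.null(config$output)) stop("config$output is required",
                                   call. = FALSE)
  spec <- default_cohort_spec(seed = config$seed)
  for (k in c("n_malignant", "n_benign", "he4_age_drift")) {
    if (!is.null(config[[k]])) spec[[k]] <- config[[k]]
  }
  .log_run("simulate", config)
  cohort <- generate_cohort(spec)
  write_cohort(cohort, config$output)
  meta <- list(tool = "romaP", version = as.character(
    utils::packageVersion("romaP")),
    seed = config$seed, config_hash = .config_hash(config),
    n_malignant = spec$n_malignant, n_benign = spec$n_benign)
  jsonlite::write_json(meta, paste0(config$output, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}

#' Score a cohort CSV with the ROMA variants
#'
#' Reads the cohort, applies [roma_score()], and writes the per-patient
#' risk CSV (input columns plus predictive indices, risk percentages,
#' stratum and classifications). Rejected input rows are reported via
#' messages.
#'
#' @param config Named list with `input`, `output`, and optionally
#'   `algorithm` (`"both"`/`"roma_p"`/`"roma"`), `cutoffs`, `equality`.
#' @return The scored data frame, invisibly.
#' @export
run_score <- function(config) {
  config <- .default_config(config)
  if (is.null(config$input) || is.null(config$output)) {
    stop("config$input and config$output are required", call. = FALSE)
  }
  .log_run("score", config)
  parsed <- read_cohort(config$input)
  if (nrow(parsed$rejected) > 0) {
    message("rejected ", nrow(parsed$rejected), " row(s): ",
            paste(sprintf("row %d (%s)", parsed$rejected$row,
                          parsed$rejected$reason), collapse = "; "))
  }
  if (nrow(parsed$cohort) == 0) stop("no valid rows in input",
                                     call. = FALSE)
  scored <- roma_score(parsed$cohort, algorithm = config$algorithm,
                       cutoffs = config$cutoffs,
                       equality = config$equality)
  write_cohort(scored, config$output)
  invisible(scored)
}

# one evaluation row: confusion metrics at the cutoff + ROC/AUC with
# DeLong CI + Youden-selected cutoff, or NAs when a class is absent
.evaluate_subset <- function(scores, labels, cutoff, subset, algorithm) {
  base <- data.frame(subset = subset, algorithm = algorithm,
                     n = length(scores),
                     n_malignant = sum(labels == "malignant"),
                     n_benign = sum(labels == "benign"),
                     cutoff = cutoff, stringsAsFactors = FALSE)
  empty <- data.frame(sensitivity = NA_real_, specificity = NA_real_,
                      ppv = NA_real_, npv = NA_real_, auc = NA_real_,
                      se_auc = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, youden_cutoff = NA_real_)
  if (base$n_malignant < 2 || base$n_benign < 2) return(cbind(base, empty))
  tab <- confusion_at_cutoff(scores, labels, cutoff)
  met <- suppressWarnings(confusion_metrics(tab))
  dl <- delong_variance(scores, labels)
  yc <- select_cutoff(scores, labels)
  cbind(base, data.frame(
    sensitivity = met$sensitivity, specificity = met$specificity,
    ppv = met$ppv, npv = met$npv, auc = dl$auc, se_auc = dl$se_auc,
    ci_low = dl$ci_auc[1], ci_high = dl$ci_auc[2],
    youden_cutoff = yc$cutoff))
}

#' Evaluate diagnostic performance of scored algorithms
#'
#' Reads a labeled cohort, scores it, and reports per algorithm and per
#' subgroup (all patients, premenopausal, postmenopausal, and each age
#' stratum) the confusion metrics at the operating cutoff together with
#' the AUC, its DeLong standard error and 95% confidence interval, and
#' the Youden-optimal cutoff. Written as CSV and, with full precision, as
#' JSON.
#'
#' @param config Named list with `input` (labeled cohort CSV), `output`
#'   (CSV path; a `.json` twin is written alongside), and the optional
#'   keys of [run_score()].
#' @return The evaluation data frame, invisibly.
#' @export
run_evaluate <- function(config) {
  config <- .default_config(config)
  if (is.null(config$input) || is.null(config$output)) {
    stop("config$input and config$output are required", call. = FALSE)
  }
  .log_run("evaluate", config)
  parsed <- read_cohort(config$input)
  cohort <- parsed$cohort[!is.na(parsed$cohort$label), ]
  if (nrow(cohort) == 0) stop("evaluation needs labeled rows",
                              call. = FALSE)
  scored <- suppressWarnings(
    roma_score(cohort, algorithm = "both", cutoffs = config$cutoffs,
               equality = config$equality))
  subsets <- list(all = rep(TRUE, nrow(scored)),
                  premenopausal = scored$menopausal_status == "pre",
                  postmenopausal = scored$menopausal_status == "post")
  for (w in unique(scored$stratum)) {
    subsets[[w]] <- scored$stratum == w
  }
  rows <- list()
  cuts <- config$cutoffs
  for (s in names(subsets)) {
    i <- subsets[[s]]
    if (!any(i)) next
    if (config$algorithm %in% c("both", "roma_p")) {
      rows[[length(rows) + 1L]] <- .evaluate_subset(
        scored$roma_p_percent[i], scored$label[i], cuts$roma_p, s, "roma_p")
    }
    if (config$algorithm %in% c("both", "roma")) {
      known <- i & !is.na(scored$roma_percent)
      if (any(known)) {
        cut_s <- if (s == "premenopausal") cuts$roma_pre
                 else if (s == "postmenopausal") cuts$roma_post
                 else cuts$roma_post  # mixed subsets: report at post cutoff
        rows[[length(rows) + 1L]] <- .evaluate_subset(
          scored$roma_percent[known], scored$label[known], cut_s, s, "roma")
      }
    }
  }
  report <- do.call(rbind, rows)
  out <- report
  pct <- c("sensitivity", "specificity", "ppv", "npv")
  out[pct] <- lapply(out[pct], round, 1)
  out[c("auc", "se_auc", "ci_low", "ci_high")] <-
    lapply(out[c("auc", "se_auc", "ci_low", "ci_high")], round, 3)
  utils::write.csv(out, config$output, row.names = FALSE, na = "")
  jsonlite::write_json(report, sub("\\.csv$", ".json", config$output),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}

#' Paired DeLong comparison matrix across markers and algorithms
#'
#' Reads a labeled cohort, computes CA125, HE4, standard-ROMA and
#' age-stratified-ROMA scores for the same patients, and reports each
#' AUC with its DeLong confidence interval plus the matrix of pairwise
#' paired DeLong p-values. Patients with unknown menopausal status are
#' excluded so all four scores are defined on the same subjects.
#'
#' @param config Named list with `input` and `output` (CSV; a `.json`
#'   twin is written alongside).
#' @return List with `auc` (data frame) and `p_matrix`, invisibly.
#' @export
run_compare <- function(config) {
  config <- .default_config(config)
  if (is.null(config$input) || is.null(config$output)) {
    stop("config$input and config$output are required", call. = FALSE)
  }
  .log_run("compare-auc", config)
  parsed <- read_cohort(config$input)
  cohort <- parsed$cohort[!is.na(parsed$cohort$label) &
                            parsed$cohort$menopausal_status %in%
                              c("pre", "post"), ]
  if (nrow(cohort) == 0) {
    stop("comparison needs labeled rows with known menopausal status",
         call. = FALSE)
  }
  scored <- suppressWarnings(roma_score(cohort, algorithm = "both"))
  markers <- list(CA125 = scored$ca125, HE4 = scored$he4,
                  ROMA = scored$roma_percent,
                  ROMA_P = scored$roma_p_percent)
  labels <- scored$label
  auc_tab <- do.call(rbind, lapply(names(markers), function(nm) {
    dl <- delong_variance(markers[[nm]], labels)
    data.frame(marker = nm, auc = dl$auc, se_auc = dl$se_auc,
               ci_low = dl$ci_auc[1], ci_high = dl$ci_auc[2],
               stringsAsFactors = FALSE)
  }))
  k <- length(markers)
  p_matrix <- matrix(NA_real_, k, k,
                     dimnames = list(names(markers), names(markers)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a != b) {
      p_matrix[a, b] <- delong_compare(markers[[a]], markers[[b]],
                                       labels)$p
    }
  }
  out <- cbind(auc_tab, as.data.frame(round(p_matrix, 4)))
  out[c("auc", "se_auc", "ci_low", "ci_high")] <-
    lapply(out[c("auc", "se_auc", "ci_low", "ci_high")], round, 3)
  utils::write.csv(out, config$output, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(auc = auc_tab, p_matrix = as.data.frame(p_matrix)),
    sub("\\.csv$", ".json", config$output),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(auc = auc_tab, p_matrix = p_matrix))
}
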