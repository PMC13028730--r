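#' Long-format single-oral-dose PK dataset
#'
#' Constructs and validates a `pk_dataset`: a long-format table of dosing
#' and observation records in the style of NONMEM/Monolix datasets. Each
#' record is either a dose event (`EVID = 1`, `AMT` in mg/kg) or an
#' observation (`EVID = 0`, `DV` in ug/mL); the design is a single oral
#' dose at time 0 per subject.
#'
#' Canonical columns: `ID` (integer subject id), `TIME` (h since first
#' dose), `AMT` (mg/kg, dose rows only), `DV` (ug/mL, observation rows
#' only), `EVID` (1 dose / 0 observation), `FORM` (factor `FREE`/`NC`),
#' `WT` (kg), `AGE` (months). An optional `EXCL` column flags rows to drop
#' on read (excluded rows are reported via a message).
#'
#' @param df data.frame with the canonical columns
#' @return a validated `pk_dataset` (data.frame subclass), rows ordered by
#'   `(ID, TIME)` with dose rows first on ties
#' @export
pk_dataset <- function(df) {
  req <- c("ID", "TIME", "AMT", "DV", "EVID", "FORM")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"WT" %in% names(df)) df$WT <- NA_real_
  if (!"AGE" %in% names(df)) df$AGE <- NA_real_

  df$ID <- as.integer(df$ID)
  df$TIME <- as.numeric(df$TIME)
  df$AMT <- as.numeric(df$AMT)
  df$DV <- as.numeric(df$DV)
  df$EVID <- as.integer(df$EVID)
  df$FORM <- .parse_form(df$FORM)

  ord <- order(df$ID, df$TIME, -df$EVID)
  df <- df[ord, c(req, "WT", "AGE"), drop = FALSE]
  rownames(df) <- NULL
  validate_pk_dataset(df)
  class(df) <- c("pk_dataset", "data.frame")
  df
}

.parse_form <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1)))
      stop("numeric FORM must be coded 0 (FREE) / 1 (NC)")
    x <- ifelse(x == 1, "NC", "FREE")
  }
  x <- toupper(as.character(x))
  bad <- !x %in% c("FREE", "NC")
  if (any(bad))
    stop("unknown formulation level(s): ", paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = c("FREE", "NC"))
}

#' Validate a PK dataset against the single-oral-dose design
#'
#' Checks the structural invariants: non-negative times, strictly positive
#' dose amounts and observed concentrations, dose/observation exclusivity,
#' exactly one dose event per subject at time 0, and no duplicated
#' observation times within a subject. Violations raise an error naming the
#' offending row or subject.
#'
#' @param df a data.frame in canonical column layout
#' @return the data.frame, invisibly
#' @export
validate_pk_dataset <- function(df) {
  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) stop(msg, " (row ", i[1], ")", call. = FALSE)
  }
  bad_row(is.na(df$ID), "missing subject id")
  bad_row(!is.finite(df$TIME) | df$TIME < 0, "negative or missing time")
  bad_row(df$EVID == 1 & (is.na(df$AMT) | df$AMT <= 0),
          "dose record must carry a positive amount")
  bad_row(df$EVID == 1 & !is.na(df$DV),
          "a record cannot be both dose and observation")
  bad_row(df$EVID == 0 & is.na(df$DV), "observation record lacks DV")
  bad_row(df$EVID == 0 & !is.na(df$AMT),
          "a record cannot be both observation and dose")
  bad_row(df$EVID == 0 & df$DV <= 0,
          "observed concentrations must be strictly positive")

  for (id in unique(df$ID)) {
    sub <- df[df$ID == id, , drop = FALSE]
    ndose <- sum(sub$EVID == 1)
    if (ndose != 1)
      stop("subject ", id, " has ", ndose,
           " dose events; the single-dose design requires exactly 1",
           call. = FALSE)
    if (sub$TIME[sub$EVID == 1] != 0)
      stop("subject ", id, " dose event is not at time 0", call. = FALSE)
    ot <- sub$TIME[sub$EVID == 0]
    if (anyDuplicated(ot))
      stop("subject ", id, " has duplicated observation times", call. = FALSE)
    if (length(unique(sub$FORM)) > 1)
      stop("subject ", id, " has inconsistent formulation codes", call. = FALSE)
  }
  invisible(df)
}

#' Read a NONMEM-style CSV into a PK dataset
#'
#' Columns may be renamed through `dialect`, a named list/vector mapping
#' canonical names to the file's names (e.g. `list(DV = "CONC")`), or a
#' path to a YAML file with the same mapping. An `MDV` column, if present
#' and unmapped, is honoured (`MDV = 1` rows with `EVID = 0` are dropped);
#' rows flagged in an `EXCL` column are dropped with a message.
#'
#' @param path CSV file path
#' @param dialect optional column-name mapping (named list or YAML path)
#' @return a [pk_dataset()]
#' @export
read_pkdata <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(dialect) && length(dialect) == 1)
    dialect <- yaml::read_yaml(dialect)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      from <- dialect[[canon]]
      if (!from %in% names(df))
        stop("dialect maps ", canon, " to absent column ", from)
      names(df)[names(df) == from] <- canon
    }
  }
  if ("MDV" %in% names(df)) {
    drop <- df$MDV == 1 & df$EVID == 0
    if (any(drop)) {
      message("dropping ", sum(drop), " MDV-flagged observation row(s)")
      df <- df[!drop, , drop = FALSE]
    }
  }
  if ("EXCL" %in% names(df)) {
    drop <- !is.na(df$EXCL) & df$EXCL != 0
    if (any(drop)) {
      message("dropping ", sum(drop), " excluded row(s): rows ",
              paste(which(drop), collapse = ", "))
      df <- df[!drop, , drop = FALSE]
    }
  }
  df$AMT[df$AMT %in% 0] <- NA_real_
  df$DV[df$EVID == 1] <- NA_real_
  pk_dataset(df)
}

#' Write a PK dataset to its canonical CSV form
#'
#' Writes the canonical header `ID,TIME,AMT,DV,EVID,FORM,WT,AGE` with the
#' formulation encoded 0 = FREE / 1 = NC (legend in a header comment) and
#' numbers at full precision, so that `read_pkdata()` round-trips exactly.
#'
#' @param data a [pk_dataset()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pkdata <- function(data, path) {
  stopifnot(inherits(data, "pk_dataset"))
  out <- as.data.frame(data)
  out$FORM <- as.integer(out$FORM == "NC")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# pkdual canonical PK dataset; FORM: 0 = FREE, 1 = NC", con)
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out)) {
    fmt <- function(x) {
      y <- vapply(x, function(v) {
        if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE)
      }, character(1))
      y
    }
    cells <- vapply(out, function(col) fmt(as.numeric(col)), character(nrow(out)))
    if (nrow(out) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Summarise study structure
#'
#' @param object a [pk_dataset()]
#' @param ... unused
#' @return a list with per-arm subject counts, observation counts per
#'   subject, total observations, and covariate ranges
#' @export
summary.pk_dataset <- function(object, ...) {
  obs <- object[object$EVID == 0, , drop = FALSE]
  subj <- unique(object[object$EVID == 1, c("ID", "FORM", "WT", "AGE")])
  res <- list(
    n_subjects = nrow(subj),
    n_per_arm = c(FREE = sum(subj$FORM == "FREE"), NC = sum(subj$FORM == "NC")),
    n_obs = nrow(obs),
    obs_per_subject = table(factor(obs$ID, levels = subj$ID)),
    dose_per_kg = unique(object$AMT[object$EVID == 1]),
    weight_range = suppressWarnings(range(subj$WT, na.rm = TRUE)),
    age_range = suppressWarnings(range(subj$AGE, na.rm = TRUE))
  )
  class(res) <- "pk_summary"
  res
}

#' @export
print.pk_summary <- function(x, ...) {
  cat("PK study: ", x$n_subjects, " subjects (",
      x$n_per_arm[["FREE"]], " FREE, ", x$n_per_arm[["NC"]], " NC), ",
      x$n_obs, " observations\n", sep = "")
  cat("dose:", paste(x$dose_per_kg, collapse = ", "), "mg/kg\n")
  if (all(is.finite(x$weight_range)))
    cat("weight:", x$weight_range[1], "-", x$weight_range[2], "kg;  age:",
        x$age_range[1], "-", x$age_range[2], "months\n")
  invisible(x)
}

# Split a dataset into per-subject pieces used by the estimation machinery:
# ids, formulation indicator, dose, observation times and concentrations.
.split_subjects <- function(data) {
  stopifnot(inherits(data, "pk_dataset"))
  obs <- data[data$EVID == 0, , drop = FALSE]
  dose <- data[data$EVID == 1, , drop = FALSE]
  ids <- dose$ID
  list(
    ids = ids,
    n = length(ids),
    dose = setNames(dose$AMT, ids),
    form = setNames(dose$FORM, ids),
    wt = setNames(dose$WT, ids),
    age = setNames(dose$AGE, ids),
    obs_id = obs$ID,
    obs_idx = match(obs$ID, ids),
    time = obs$TIME,
    dv = obs$DV
  )
}
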