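# Versioned fixture tables and their cross-validation.

#' Load and validate the fixture set
#'
#' Reads the Chi definitions, rotamer inventory, bin model, radii and
#' side-chain templates from a directory (default: the installed package
#' fixtures) and cross-checks them: every inventory label must parse into
#' per-Chi symbols whose arity matches the amino acid's Chi count, every
#' mode vector must have exactly that many entries, and the ARG inventory
#' must contain no Chi5-bearing label.
#'
#' @param dir fixture directory.
#' @return list with elements `chi_definitions`, `inventory`, `bin_model`,
#'   `radii`, `templates`, `census`, and `hashes` (MD5 per file).
#' @export
load_fixtures <- function(dir = system.file("extdata", package = "rotaudit")) {
  files <- c(chi_definitions = "chi_definitions.tsv",
             inventory = "rotamer_inventory.tsv",
             bin_model = "bin_model.json",
             radii = "radii.tsv",
             templates = "sidechain_templates.tsv",
             census = "reference_census.tsv")
  paths <- file.path(dir, files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("fixture file(s) missing: ", paste(files[missing], collapse = ", "))
  }
  fx <- list(chi_definitions = chi_definitions(paths[1]),
             inventory = rotamer_inventory(paths[2]),
             bin_model = bin_model(paths[3]),
             radii = vdw_radii(paths[4]),
             templates = sidechain_templates(paths[5]),
             census = utils::read.delim(paths[6], stringsAsFactors = FALSE))
  kchi <- table(fx$chi_definitions$aa)
  inv <- fx$inventory
  for (i in seq_len(nrow(inv))) {
    aa <- inv$aa[i]; label <- inv$label[i]
    if (!aa %in% names(kchi)) {
      stop("inventory row ", i, ": unknown amino acid '", aa, "'")
    }
    k <- kchi[[aa]]
    modes <- unlist(inv[i, paste0("mode", 1:4)])
    if (label == "off") next
    nmode <- sum(!is.na(modes))
    expected <- if (aa == "PRO") 1L else k
    if (nmode != expected) {
      stop("inventory row ", i, " (", aa, " '", label, "'): ", nmode,
           " modes but ", expected, " Chi angles expected")
    }
    if (aa == "PRO") next
    m <- regmatches(label, regexec("^([ptm]+)(-?[0-9]+)?$", label))[[1]]
    if (length(m) < 2 || m[1] == "") {
      stop("inventory row ", i, " (", aa, "): unparseable label '", label, "'")
    }
    nsym <- nchar(m[2]) + (m[3] != "")
    if (nsym != k) {
      stop("inventory row ", i, " (", aa, " '", label, "'): label arity ",
           nsym, " does not match ", k, " Chi angles")
    }
  }
  if (any(kchi[["ARG"]] != 4) || any(nchar(sub("-?[0-9]+$", "",
      inv$label[inv$aa == "ARG" & inv$label != "off"])) > 3)) {
    stop("ARG inventory must not carry Chi5-bearing labels")
  }
  fx$hashes <- tools::md5sum(paths)
  names(fx$hashes) <- files
  fx
}
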