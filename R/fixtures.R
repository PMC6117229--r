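# Deterministic worked-example substance libraries. Structures are
# curated literature SMILES (nicotine and isomers, PFOS, the two
# nicarbazin components, methapyrilene, raloxifene, chlorotriazines);
# where only counts of a result set are published, the library is
# engineered to satisfy every stated count (e.g. the nicotine set: 8
# MS-Ready hits, 5 exact hits, the nicotine structure in 6 substances)
# without claiming to mirror the unpublished identities.

.fx <- list()

.smi <- list(
  nicotine_s = "CN1CCC[C@H]1c1cccnc1",
  nicotine_r = "CN1CCC[C@@H]1c1cccnc1",
  nicotine = "CN1CCCC1c1cccnc1",
  anabasine = "C1CCC(NC1)c1cccnc1",
  mepyrrolidine = "CN1CCCC1c1ccncc1",  # 1-methyl-2-(pyridin-4-yl)pyrrolidine
  salicylic = "OC(=O)c1ccccc1O",
  menthol = "CC(C)C1CCC(C)CC1O",
  pfos = "OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
  pfos_anion = "[O-]S(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
  pfoa = "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
  dinitrocarbanilide =
    "O=C(Nc1ccc(cc1)[N+](=O)[O-])Nc1ccc(cc1)[N+](=O)[O-]",
  hdp = "Cc1cc(C)nc(O)n1",  # 2-hydroxy-4,6-dimethylpyrimidine
  methapyrilene = "CN(C)CCN(Cc1cccs1)c1ccccn1",
  fumaric = "OC(=O)/C=C/C(=O)O",
  raloxifene = paste0("OC1=CC2=C(C=C1)SC(=C2C(=O)c1ccc(OCCN2CCCCC2)cc1)",
                      "c1ccc(O)cc1"),
  terbutylazine = "CCNc1nc(Cl)nc(NC(C)(C)C)n1",
  propazine = "CC(C)Nc1nc(Cl)nc(NC(C)C)n1",
  sebutylazine = "CCNc1nc(Cl)nc(NC(C)CC)n1",
  simazine = "CCNc1nc(Cl)nc(NCC)n1",
  desethylterbutylazine = "Nc1nc(Cl)nc(NC(C)(C)C)n1",
  citric = "OC(=O)CC(O)(CC(=O)O)C(=O)O",
  methylium = paste0("CC([O-])=O.CCN(CC)c1ccc(cc1)[C+](c1ccc(N(CC)CC)cc1)",
                     "c1ccc(N(CC)CC)cc1")
)

fixture_names <- c("nicotine_family", "pfos_family", "nicarbazin",
                   "methapyrilene", "raloxifene", "triazines",
                   "salt_errors")

#' Build a worked-example substance library
#'
#' Deterministic fixture libraries used throughout the documentation and
#' tests: no randomness, fixed content, every SMILES parses.
#'
#' @param name One of `"nicotine_family"` (3 stereo forms of nicotine, 2
#'   constitutional C10H14N2 isomers, 3 multi-component nicotine
#'   substances), `"pfos_family"` (neutral acid, sulfonate salts, a
#'   mixture), `"nicarbazin"`, `"methapyrilene"` (free base + the 3:2
#'   fumarate), `"raloxifene"` (hydrochloride), `"triazines"` (the five
#'   chlorotriazines with a scoring metadata table plus simazine
#'   salt/mixture variants) or `"salt_errors"` (a permanently charged
#'   triarylmethylium acetate).
#' @return An `msr_fixture`: list with `name`, `substances` (tibble:
#'   `id`, `name`, `smiles`, `data_sources`, and for `"triazines"` the
#'   metadata columns `pubmed_count`, `norman`, `stoffident`,
#'   `toxcast_pct_active`), `description`.
#' @examples
#' build_fixture("nicarbazin")$substances$name
#' @export
build_fixture <- function(name) {
  if (!name %in% fixture_names) {
    stop("unknown fixture '", name, "'; choose one of: ",
         paste(fixture_names, collapse = ", "), call. = FALSE)
  }
  s <- .smi
  lib <- switch(name,
    nicotine_family = list(
      substances = tibble::tibble(
        id = paste0("NIC", 1:8),
        name = c("(S)-nicotine", "(R)-nicotine", "nicotine",
                 "anabasine", "1-methyl-2-(pyridin-4-yl)pyrrolidine",
                 "nicotine hydrochloride", "nicotine salicylate",
                 "nicotine-menthol mixture"),
        smiles = c(s$nicotine_s, s$nicotine_r, s$nicotine, s$anabasine,
                   s$mepyrrolidine,
                   paste0(s$nicotine_s, ".Cl"),
                   paste0(s$nicotine_s, ".", s$salicylic),
                   paste0(s$nicotine, ".", s$menthol)),
        data_sources = c(50L, 10L, 40L, 20L, 5L, 15L, 8L, 3L)
      ),
      description = paste("8 nicotine-related substances: MS-Ready",
                          "formula search for C10H14N2 returns 8, exact",
                          "search 5, the nicotine structure is a",
                          "component of 6")
    ),
    pfos_family = list(
      substances = tibble::tibble(
        id = paste0("PFS", 1:4),
        name = c("perfluorooctanesulfonic acid", "PFOS potassium salt",
                 "PFOS ammonium salt", "PFOS-PFOA mixture"),
        smiles = c(s$pfos,
                   paste0("[K+].", s$pfos_anion),
                   paste0("[NH4+].", s$pfos_anion),
                   paste0(s$pfos, ".", s$pfoa)),
        data_sources = c(60L, 30L, 12L, 4L)
      ),
      description = paste("neutral acid, two sulfonate salts and a",
                          "mixture; all share the C8HF17O3S MS-Ready",
                          "form")
    ),
    nicarbazin = list(
      substances = tibble::tibble(
        id = "NCZ1", name = "nicarbazin",
        smiles = paste0(s$dinitrocarbanilide, ".", s$hdp),
        data_sources = 25L
      ),
      description = paste("two-component coccidiostat; components",
                          "C13H10N4O5 and C6H8N2O, overall C19H18N6O6")
    ),
    methapyrilene = list(
      substances = tibble::tibble(
        id = c("MTP1", "MTP2"),
        name = c("methapyrilene", "methapyrilene fumarate"),
        smiles = c(s$methapyrilene,
                   paste(c(rep(s$methapyrilene, 3), rep(s$fumaric, 2)),
                         collapse = ".")),
        data_sources = c(35L, 9L)
      ),
      description = "free base and the 3:2 fumarate mixture"
    ),
    raloxifene = list(
      substances = tibble::tibble(
        id = "RLX1", name = "raloxifene hydrochloride",
        smiles = paste0(s$raloxifene, ".Cl"),
        data_sources = 45L
      ),
      description = "hydrochloride salt; HCl stripped by the workflow"
    ),
    triazines = list(
      substances = tibble::tibble(
        id = paste0("TRZ", 1:7),
        name = c("terbutylazine", "propazine", "sebutylazine",
                 "simazine", "desethylterbutylazine",
                 "simazine hydrochloride", "simazine citrate mixture"),
        smiles = c(s$terbutylazine, s$propazine, s$sebutylazine,
                   s$simazine, s$desethylterbutylazine,
                   paste0(s$simazine, ".Cl"),
                   paste0(s$simazine, ".", s$citric)),
        data_sources = c(3880L, 1560L, 182L, 3000L, 400L, 20L, 10L),
        pubmed_count = c(540L, 900L, 12L, 1200L, 0L, NA, NA),
        norman = c(1L, 1L, 0L, 1L, 1L, NA, NA),
        stoffident = c(1L, 1L, 1L, 1L, 1L, NA, NA),
        toxcast_pct_active = c(32, 45, NA, 60, NA, NA, NA)
      ),
      description = paste("the five chlorotriazines of the collaborative",
                          "trial annotations with a synthetic scoring",
                          "metadata table, plus simazine salt/mixture",
                          "variants")
    ),
    salt_errors = list(
      substances = tibble::tibble(
        id = "SLT1",
        name = "tris[4-(diethylamino)phenyl]methylium acetate",
        smiles = s$methylium,
        data_sources = 2L
      ),
      description = paste("salt whose cation keeps a permanent charge;",
                          "the acetate counterion is desalted")
    )
  )
  structure(c(list(name = name), lib), class = "msr_fixture")
}

#' @export
print.msr_fixture <- function(x, ...) {
  cat("<msr_fixture> ", x$name, ": ", nrow(x$substances),
      " substance(s)\n  ", x$description, "\n", sep = "")
  invisible(x)
}

#' Write a fixture library to disk
#'
#' Writes `<name>.sdf` (explicit-hydrogen structures with id/name/
#' data_sources fields) and `<name>_metadata.tsv`. Output is byte-stable:
#' re-running produces identical files.
#'
#' @param library An `msr_fixture` from [build_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture <- function(library, dir) {
  stopifnot(inherits(library, "msr_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subs <- library$substances
  sdf <- file.path(dir, paste0(library$name, ".sdf"))
  write_sdf_records(
    subs$smiles, sdf, titles = subs$id,
    fields = list(id = subs$id, name = subs$name,
                  data_sources = as.character(subs$data_sources))
  )
  tsv <- file.path(dir, paste0(library$name, "_metadata.tsv"))
  readr::write_tsv(dplyr::select(subs, -"smiles"), tsv)
  invisible(c(sdf = sdf, metadata = tsv))
}
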