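# Physicochemical property vectors used for decoy matching: molecular
# weight, cLogP, rotatable bonds, H-bond acceptors/donors and net charge at
# physiological pH (rule-based protonation).

SMARTS_ROTATABLE <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
SMARTS_CARBOXYLIC <- "[CX3](=O)[OX2H1]"
# aliphatic amines (primary/secondary/tertiary), excluding anilines,
# amides, sulfonamides and any N engaged in multiple bonding
SMARTS_ALIPHATIC_AMINE <-
  "[NX3;+0;!$(Nc);!$(NC=O);!$(NC=S);!$(NS=O);!$(N=*);!$(N#*);!$(N~[#7,#8])]"

#' Physicochemical property vectors
#'
#' Six matched properties per molecule: molecular weight, cLogP, rotatable
#' bonds, H-bond acceptors, H-bond donors, and the net charge at pH 7.4
#' from a rule-based protonation model (each neutral carboxylic acid
#' contributes -1, each neutral aliphatic amine +1, added to the formal
#' charge).
#'
#' @param smiles character vector of SMILES (named by molecule id if
#'   available).
#' @return data.frame with columns `mw` (Da), `clogp`, `rotatable_bonds`,
#'   `hba`, `hbd`, `net_charge`; rownames are molecule ids.
#' @export
property_vector <- function(smiles) {
  nms <- names(smiles)
  if (is.null(nms)) nms <- paste0("m", seq_along(smiles))
  ps <- parse_smiles_set(stats::setNames(smiles, nms))
  if (!all(ps$ok)) {
    stop("unparseable SMILES: ",
         paste(utils::head(nms[!ps$ok], 5), collapse = ", "))
  }
  props <- ChemmineR::propOB(ps$sdf)
  rot <- as.integer(ChemmineR::smartsSearchOB(ps$sdf, SMARTS_ROTATABLE))
  cooh <- as.integer(ChemmineR::smartsSearchOB(ps$sdf, SMARTS_CARBOXYLIC))
  amine <- as.integer(ChemmineR::smartsSearchOB(ps$sdf,
                                                SMARTS_ALIPHATIC_AMINE))
  graphs <- mol_graphs(ps$sdf)
  formal <- vapply(graphs, function(g) sum(g$charge), numeric(1))
  out <- data.frame(
    mw = as.numeric(props$MW),
    clogp = as.numeric(props$logP),
    rotatable_bonds = rot,
    hba = as.integer(props$HBA2),
    hbd = as.integer(props$HBD),
    net_charge = as.integer(formal - cooh + amine),
    row.names = nms
  )
  out
}
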