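## Curated CYP51A1 variant and occupancy tables bundled with the package.
## Residue numbering follows the NP_000777.1 reference sequence. Printed
## SIFT/PolyPhen-2 labels are stored verbatim (including their internal
## inconsistencies, which consistencyCheck() surfaces); scores are the
## printed scores.

table3Damaging <- function() {
  df <- utils::read.table(header = TRUE, sep = ";", strip.white = TRUE, quote = "",
                          stringsAsFactors = FALSE, text = "
snp_id;sift_label_printed;sift_score;polyphen_label_printed;polyphen_score;protein_change;region
rs372875744;Damaging;0.03;Probably damaging;0.993;N125H;Helix B
rs535433995;Damaging;0.01;Probably damaging;0.975;H177R;Helix D
rs151249652;Damaging;0.01;Probably damaging;0.984;E194C;Beta sheet 3-1
rs536125410;Damaging;0;Probably damaging;0.982;L253S;Loop between helix F''/G, surface
rs141009880;Damaging;0.01;Possibly damaging;0.892;I274T;Helix G
rs140702410;Damaging;0;Probably damaging;0.969;R277L;Helix G
rs140118347;Damaging;0.02;Possibly damaging;0.799;A334S;Helix I
rs554366054;Damaging;0.02;Probably damaging;1;L417R;Loop between helix K' and meander, surface
rs138109473;Damaging;0;Probably damaging;0.974;R431H;Meander
rs542915180;Damaging;0;Probably damaging;0.999;R454H;Cys pocket
rs563098505;Damaging;0;Probably damaging;0.98;Y462D;Helix L, next to cys pocket
rs553164028;damaging;0;Probably damaging;0.997;R507K;C-terminal of the protein
")
  df
}

table4ConservedRegions <- function() {
  df <- utils::read.table(header = TRUE, sep = ";", strip.white = TRUE, quote = "",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          text = "
snp_id;protein_change;polyphen_label_printed;polyphen_score;sift_label_printed;sift_score;region;note
rs368261783;Y137C;Possibly damaging;0.497;damaging;0;SRS1;NA
rs750743669;S138N;Benign;0.262;damaging;0.04;SRS1;NA
rs758553106;R139C;Probably damaging;0.946;damaging;0.03;SRS1;NA
rs140356336;R139H;Benign;0.029;tolerated;0.65;SRS1;NA
COSM5500428;V144A;Probably damaging;0.994;tolerated;0.29;SRS1;NA
rs312262912;Y151D;Probably damaging;0.962;damaging;0;SRS1;NA
rs371492794;D152G;Probably damaging;0.988;damaging;0.01;SRS1;NA
COSM1202901 rs755026542;D152N;Probably damaging;0.985;damaging;0.01;SRS1;NA
rs776271983;A172V;Benign;0.101;tolerated;0.22;POR interaction;NA
/;L232P;Probably damaging;0.995;damaging;0;SRS2;NA
COSM353554;Y233*;NA;NA;NA;NA;SRS2;Unknown
COSM2863985;W245S;Probably damaging;0.981;damaging;0.01;Azole interaction;NA
rs753673809;W245Ter;NA;NA;NA;NA;Azole interaction;No protein
COSM1579448;W250S;Probably damaging;0.999;damaging;0.02;Azole interaction;NA
rs200921006 COSM3663398;R258C;Probably damaging;0.999;damaging;0;SRS3;NA
rs765961879 COSM1202902;R258H;Benign;0.93;damaging;0;SRS3;NA
rs765961879;R258L;Benign;0.168;damaging;0.01;SRS3;NA
rs745413412;H320P;Possibly damaging;0.899;damaging;0;SRS4;NA
rs377725460;T325A;Benign;0.359;damaging;0.01;SRS4;NA
rs760669078;P381T;Probably damaging;0.990;tolerated;0.08;SRS5;NA
rs150090274;I383V;Benign;0.024;damaging;0.05;SRS5;NA
rs150090274;I383L;Benign;0.143;tolerated;0.14;SRS5;NA
COSM3698597;M384I;Probably damaging;0.930;tolerated;0.34;SRS5;NA
rs759341868;I385F;Benign;0.075;damaging;0.01;SRS5;NA
rs773893086;M386V;Benign;0.376;tolerated;0.12;SRS5;NA
rs532896478;M386I;Benign;0.044;tolerated;1;SRS5;NA
rs765119371;M387I;Possibly damaging;0.758;damaging;0.05;SRS5;NA
COSM5986705;M387delM;NA;NA;NA;NA;SRS5;Unknown
rs748782320;R388Ter;NA;NA;NA;NA;SRS5;No protein
rs528934873;R452H;Benign;0.082;damaging;0.04;POR interaction;NA
rs779786966;R452C;Benign;0.166;damaging;0;POR interaction;NA
rs768113032;T492A;Benign;0.117;tolerated;0.15;SRS6;NA
rs749633381;M493V;Possibly damaging;0.545;damaging;0.02;SRS6;NA
")
  df
}

table5Occupancy <- function() {
  utils::read.table(header = TRUE, sep = ";", strip.white = TRUE, quote = "",
                    stringsAsFactors = FALSE, text = "
structure_label;residue;occupancy_percent
WT;M384;24.5
WT;I385;65.9
WT;I383;1.5
R277L;M384;12.7
R277L;I385;30.1
R277L;I383;0.8
R431H;M493;6.3
R431H;I494;1.2
D152G;W245;10.8
D152G;M493;1.6
D152G;F240;0.8
")
}

table1Phenotypes <- function() {
  utils::read.table(header = TRUE, sep = ";", strip.white = TRUE, quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA", text = "
cdna;protein_change;phenotype;snp_id;population_frequency
c.1263G>A;W421Ter;Infantile onset cataract, developmental delay, white-matter abnormality, neonatal liver cirrhosis, spastic diplegia, increased lanosterol;rs141654764;0.00001647
c.935T>C;I312T;Infantile onset cataract, developmental delay, white-matter abnormality, neonatal liver cirrhosis, spastic diplegia, increased lanosterol;/;NA
c.829C>T;R277C;Congenital cataract, neurologically and systemically normal;rs944015648;NA
c.695T>C;L232P;Congenital cataract, neonatal fulminant hepatic failure, global developmental delay;/;NA
c.56T>C;V19A;Association with HDL-C level;rs2229188;0.00000825
c.56T>C;V19A;Association with hypertension;rs2229188;0.00000825
c.56T>C;V19A;Negative association with lifespan;rs2229188;0.00000825
c.595+66A>G;/;Association with spontaneous premature labor;rs57218044;0.0363
c.1359T>C;/;Association with spontaneous premature labor;rs7797834;0.3596
c.*251G>C;/;Association with spontaneous premature labor;rs7793861;0.3644
c.*377T>C;/;Association with lower LDL-C and TC in second trimester;rs6465348;0.3576
c.*1016C>T;/;Association with spontaneous premature labor;rs12673910;0.1697
c.251G>C;/;Associated with glycemic HbA1c and expression of genes in pancreas;rs7793861;0.3644
")
}

table2InvitroPairs <- function() {
  utils::read.table(header = TRUE, sep = ";", strip.white = TRUE, quote = "",
                    stringsAsFactors = FALSE, text = "
human_snp;invitro_mutant;mutant_effect;predicted_human_effect
Y137C;ratY131F/S;No protein, no activity;No activity
Y137C;humanY137F;55% expression, no activity, spectrum ok;No activity
Y137C;humanY137A;Decrease in binding of substrate;No activity
R139H;ratR133G;Normal activity;Unknown
D152G/N;ratD146A;Normal expression, 106% activity;Decreased activity
D152G/N;humanD152A;70% expression, 54% activity, 4x lower turnover;Decreased activity
Y233*;ratY227F;55% activity;Lower activity
H242R;humanH242A;Destabilization of the protein;Unknown effect
H320P;ratH314F/A/K/D;Lower activity (42.6, 34.9, 20.2, 14);Lower activity
H320P;humanH320A;Destabilization, higher affinity for products;Lower activity
T325A;ratT319A;Normal activity;Normal activity
R383V/L;humanR383A;Decrease in binding of substrate;Unknown
R388Ter;ratR382A;No protein;No protein
T492A;ratT486A;Normal activity;Normal activity
T496I;ratT490A;Normal activity;Normal activity
E375*;ratE369A;No protein;No protein
")
}

#' Write the bundled variant/occupancy fixtures as TSV files
#'
#' Emits the five curated tables -- phenotype-associated variants, in-vitro
#' mutant pairs, the damaging-by-both-predictors variants (12 rows), the
#' conserved-region missense variants (33 rows) and the hydrogen-bond
#' occupancy reference table -- as plain TSV files. The writer is
#' deterministic: re-running it produces byte-identical files.
#'
#' @param outdir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
writeFixtures <- function(outdir) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stopf("cannot create directory %s", outdir)
  tabs <- list(table1_phenotypes = table1Phenotypes(),
               table2_invitro_pairs = table2InvitroPairs(),
               table3_damaging = table3Damaging(),
               table4_conserved_regions = table4ConservedRegions(),
               table5_occupancy = table5Occupancy())
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    df <- tabs[[nm]]
    con <- file(p, "wb")  # fixed eol regardless of platform
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", eol = "\n")
    close(con)
    p
  }, "")
  invisible(unname(paths))
}

#' Path to a packaged variant fixture
#'
#' @param name one of \code{"table1_phenotypes"},
#'   \code{"table2_invitro_pairs"}, \code{"table3_damaging"},
#'   \code{"table4_conserved_regions"}, \code{"table5_occupancy"}.
#' @return path to the installed TSV file.
#' @export
variantFixturePath <- function(name = c("table3_damaging",
                                        "table4_conserved_regions",
                                        "table5_occupancy",
                                        "table1_phenotypes",
                                        "table2_invitro_pairs")) {
  name <- match.arg(name)
  p <- system.file("extdata", paste0(name, ".tsv"), package = "cyp51md",
                   mustWork = FALSE)
  if (!nzchar(p) || !file.exists(p))
    stopf("fixture %s not found in installed package", name)
  p
}
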