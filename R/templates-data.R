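# Generated sidechain internal-coordinate templates (ideal residue geometry).
# Columns: atom ref1 ref2 ref3 bond angle ttype tval; torsion = tval or chi_k + tval.
.aa_templates <- list(
  ALA = data.frame(atom = c("O","CB"), ref1 = c("N","C"), ref2 = c("CA","N"), ref3 = c("C","CA"),
    bond = c(1.2070,1.5294), angle = c(120.031,109.465), ttype = c("fixed","fixed"), tval = c(-29.900,-119.999), stringsAsFactors = FALSE),
  ARG = data.frame(atom = c("O","CB","CG","CD","NE","CZ","NH1","NH2"), ref1 = c("N","C","N","CA","CB","CG","CD","CD"), ref2 = c("CA","N","CA","CB","CG","CD","NE","NE"), ref3 = c("C","CA","CB","CG","CD","NE","CZ","CZ"),
    bond = c(1.2241,1.5363,1.5371,1.5273,1.4435,1.4058,1.3906,1.3912), angle = c(125.485,111.550,114.536,112.417,111.016,123.005,120.996,119.815), ttype = c("fixed","fixed","chi1","chi2","chi3","chi4","fixed","fixed"), tval = c(-3.931,-123.561,0.000,0.000,0.000,0.000,179.986,-0.012), stringsAsFactors = FALSE),
  ASN = data.frame(atom = c("O","CB","CG","OD1","ND2"), ref1 = c("N","C","N","CA","CA"), ref2 = c("CA","N","CA","CB","CB"), ref3 = c("C","CA","CB","CG","CG"),
    bond = c(1.2079,1.5309,1.5066,1.2133,1.3476), angle = c(119.972,109.454,109.484,119.974,120.012), ttype = c("fixed","fixed","chi1","chi2","chi2"), tval = c(-19.971,-119.996,0.000,0.000,-179.926), stringsAsFactors = FALSE),
  ASP = data.frame(atom = c("O","CB","CG","OD1","OD2"), ref1 = c("N","C","N","CA","CA"), ref2 = c("CA","N","CA","CB","CB"), ref3 = c("C","CA","CB","CG","CG"),
    bond = c(1.2091,1.5301,1.5075,1.2080,1.3415), angle = c(119.984,109.480,109.463,119.959,119.999), ttype = c("fixed","fixed","chi1","chi2","chi2"), tval = c(-20.024,-120.011,0.000,0.000,-179.936), stringsAsFactors = FALSE),
  CYS = data.frame(atom = c("O","CB","SG","HG"), ref1 = c("N","C","N","CA"), ref2 = c("CA","N","CA","CB"), ref3 = c("C","CA","CB","SG"),
    bond = c(1.2068,1.5285,1.8141,1.3444), angle = c(120.060,109.496,109.498,100.034), ttype = c("fixed","fixed","chi1","fixed"), tval = c(-30.019,-120.014,0.000,-179.962), stringsAsFactors = FALSE),
  GLN = data.frame(atom = c("O","CB","CG","CD","OE1","NE2"), ref1 = c("N","C","N","CA","CB","CB"), ref2 = c("CA","N","CA","CB","CG","CG"), ref3 = c("C","CA","CB","CG","CD","CD"),
    bond = c(1.2072,1.5288,1.5284,1.5066,1.2122,1.3471), angle = c(120.033,109.459,109.534,109.543,119.937,120.093), ttype = c("fixed","fixed","chi1","chi2","chi3","chi3"), tval = c(-30.007,-120.066,0.000,0.000,0.000,-179.957), stringsAsFactors = FALSE),
  GLU = data.frame(atom = c("O","CB","CG","CD","OE1","OE2"), ref1 = c("N","C","N","CA","CB","CB"), ref2 = c("CA","N","CA","CB","CG","CG"), ref3 = c("C","CA","CB","CG","CD","CD"),
    bond = c(1.2083,1.5302,1.5306,1.5076,1.2084,1.3425), angle = c(119.981,109.482,109.402,109.430,120.003,119.998), ttype = c("fixed","fixed","chi1","chi2","chi3","chi3"), tval = c(-19.979,-119.956,0.000,0.000,0.000,-179.937), stringsAsFactors = FALSE),
  GLY = data.frame(atom = c("O"), ref1 = c("N"), ref2 = c("CA"), ref3 = c("C"),
    bond = c(1.2081), angle = c(120.051), ttype = c("fixed"), tval = c(0.018), stringsAsFactors = FALSE),
  HIS = data.frame(atom = c("O","CB","CG","ND1","CD2","CE1","NE2"), ref1 = c("N","C","N","CA","CA","CB","CB"), ref2 = c("CA","N","CA","CB","CB","CG","CG"), ref3 = c("C","CA","CB","CG","CG","ND1","CD2"),
    bond = c(1.2269,1.5337,1.5100,1.3513,1.3376,1.3369,1.3739), angle = c(122.981,111.125,112.979,120.329,129.928,107.862,105.332), ttype = c("fixed","fixed","chi1","chi2","chi2","fixed","fixed"), tval = c(-34.461,-122.779,0.000,0.000,179.846,179.905,-179.864), stringsAsFactors = FALSE),
  ILE = data.frame(atom = c("O","CB","CG1","CG2","CD1"), ref1 = c("N","C","N","N","CA"), ref2 = c("CA","N","CA","CA","CB"), ref3 = c("C","CA","CB","CB","CG1"),
    bond = c(1.2075,1.5288,1.5294,1.5303,1.5288), angle = c(120.000,109.430,109.547,109.458,109.547), ttype = c("fixed","fixed","chi1","chi1","chi2"), tval = c(-30.057,-120.073,0.000,-119.972,0.000), stringsAsFactors = FALSE),
  LEU = data.frame(atom = c("O","CB","CG","CD1","CD2"), ref1 = c("N","C","N","CA","CA"), ref2 = c("CA","N","CA","CB","CB"), ref3 = c("C","CA","CB","CG","CG"),
    bond = c(1.2077,1.5286,1.5303,1.5300,1.5285), angle = c(120.089,109.416,109.495,109.500,109.501), ttype = c("fixed","fixed","chi1","chi2","chi2"), tval = c(-29.981,-119.973,0.000,0.000,120.092), stringsAsFactors = FALSE),
  LYS = data.frame(atom = c("O","CB","CG","CD","CE","NZ"), ref1 = c("N","C","N","CA","CB","CG"), ref2 = c("CA","N","CA","CB","CG","CD"), ref3 = c("C","CA","CB","CG","CD","CE"),
    bond = c(1.2079,1.5300,1.5307,1.5308,1.5291,1.4694), angle = c(120.026,109.453,109.418,109.441,109.465,109.500), ttype = c("fixed","fixed","chi1","chi2","chi3","chi4"), tval = c(-20.009,-119.967,0.000,0.000,0.000,0.000), stringsAsFactors = FALSE),
  MET = data.frame(atom = c("O","CB","CG","SD","CE"), ref1 = c("N","C","N","CA","CB"), ref2 = c("CA","N","CA","CB","CG"), ref3 = c("C","CA","CB","CG","SD"),
    bond = c(1.2072,1.5294,1.5284,1.8137,1.8135), angle = c(120.054,109.427,109.545,109.506,100.034), ttype = c("fixed","fixed","chi1","chi2","chi3"), tval = c(-30.016,-120.037,0.000,0.000,0.000), stringsAsFactors = FALSE),
  PHE = data.frame(atom = c("O","CB","CG","CD1","CD2","CE1","CE2","CZ"), ref1 = c("N","C","N","CA","CA","CB","CB","CG"), ref2 = c("CA","N","CA","CB","CB","CG","CG","CD1"), ref3 = c("C","CA","CB","CG","CG","CD1","CD2","CE1"),
    bond = c(1.2070,1.5289,1.5052,1.3817,1.3832,1.3820,1.3819,1.3806), angle = c(119.983,109.474,109.517,120.058,120.005,120.029,119.977,120.047), ttype = c("fixed","fixed","chi1","chi2","chi2","fixed","fixed","fixed"), tval = c(-30.055,-120.094,0.000,0.000,179.758,179.994,179.839,-0.048), stringsAsFactors = FALSE),
  PRO = data.frame(atom = c("O","CB","CG","CD"), ref1 = c("N","C","N","C"), ref2 = c("CA","N","CA","CA"), ref3 = c("C","CA","CB","N"),
    bond = c(1.2085,1.5434,1.5426,1.4866), angle = c(119.989,104.722,105.059,104.136), ttype = c("fixed","fixed","chi1","fixed"), tval = c(-16.989,-118.841,0.000,158.143), stringsAsFactors = FALSE),
  SER = data.frame(atom = c("O","CB","OG","HG"), ref1 = c("N","C","N","CA"), ref2 = c("CA","N","CA","CB"), ref3 = c("C","CA","CB","OG"),
    bond = c(1.2069,1.5287,1.4283,0.9670), angle = c(120.047,109.471,109.512,106.814), ttype = c("fixed","fixed","chi1","fixed"), tval = c(-30.006,-120.020,0.000,-179.969), stringsAsFactors = FALSE),
  THR = data.frame(atom = c("O","CB","OG1","CG2","HG1"), ref1 = c("N","C","N","N","CA"), ref2 = c("CA","N","CA","CA","CB"), ref3 = c("C","CA","CB","CB","OG1"),
    bond = c(1.2071,1.5290,1.4280,1.5301,0.9666), angle = c(120.093,109.411,109.505,109.525,106.813), ttype = c("fixed","fixed","chi1","chi1","fixed"), tval = c(-30.018,-120.000,0.000,-120.031,-60.056), stringsAsFactors = FALSE),
  TRP = data.frame(atom = c("O","CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"), ref1 = c("N","C","N","CA","CA","CB","CB","CB","CG","CG","CD2"), ref2 = c("CA","N","CA","CB","CB","CG","CG","CG","CD2","CD2","CE2"), ref3 = c("C","CA","CB","CG","CG","CD1","CD2","CD2","CE2","CE3","CZ2"),
    bond = c(1.2079,1.5286,1.5067,1.3426,1.4639,1.3686,1.4068,1.3961,1.3906,1.3659,1.3773), angle = c(119.998,109.523,109.442,126.496,126.512,109.932,106.076,134.047,119.346,119.795,119.806), ttype = c("fixed","fixed","chi1","chi2","chi2","fixed","fixed","fixed","fixed","fixed","fixed"), tval = c(-30.000,-120.026,0.000,0.000,179.622,179.944,179.958,0.784,-179.825,179.639,0.221), stringsAsFactors = FALSE),
  TYR = data.frame(atom = c("O","CB","CG","CD1","CD2","CE1","CE2","CZ","OH"), ref1 = c("N","C","N","CA","CA","CB","CB","CG","CD1"), ref2 = c("CA","N","CA","CB","CB","CG","CG","CD1","CE1"), ref3 = c("C","CA","CB","CG","CG","CD1","CD2","CE1","CZ"),
    bond = c(1.2070,1.5287,1.5062,1.3823,1.3830,1.3810,1.3809,1.3867,1.3582), angle = c(120.008,109.470,109.497,119.947,119.943,120.073,120.020,119.978,120.130), ttype = c("fixed","fixed","chi1","chi2","chi2","fixed","fixed","fixed","fixed"), tval = c(-29.977,-120.041,0.000,0.000,179.692,-179.976,179.775,-0.102,-179.966), stringsAsFactors = FALSE),
  VAL = data.frame(atom = c("O","CB","CG1","CG2"), ref1 = c("N","C","N","N"), ref2 = c("CA","N","CA","CA"), ref3 = c("C","CA","CB","CB"),
    bond = c(1.2075,1.5287,1.5299,1.5292), angle = c(120.025,109.445,109.509,109.490), ttype = c("fixed","fixed","chi1","chi1"), tval = c(-30.000,-120.004,0.000,120.026), stringsAsFactors = FALSE)
)

# chi dihedral atom quadruples
.chi_defs <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"), c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

# template (ideal-geometry) chi values, used as defaults in tests/fixtures
.template_chi <- list(
  ARG = c(63.801,177.631,60.183,179.976),
  ASN = c(-64.948,-0.055),
  ASP = c(-64.988,-0.061),
  CYS = c(-59.998),
  GLN = c(-59.924,-179.992,-0.055),
  GLU = c(-65.014,-179.998,-0.033),
  HIS = c(-158.204,-90.010),
  ILE = c(-59.994,180.000),
  LEU = c(-60.068,179.985),
  LYS = c(-65.021,180.000,179.997,-179.951),
  MET = c(-60.017,-179.985,-179.995),
  PHE = c(-59.932,89.968),
  PRO = c(-23.800,0.025),
  SER = c(-59.969),
  THR = c(60.022),
  TRP = c(-60.001,90.038),
  TYR = c(-59.981,90.030),
  VAL = c(-59.994)
)
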