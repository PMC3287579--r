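# ABA stomatal-closure network -- USER-TRANSCRIPTION TEMPLATE (synthetic stub)
#
# This file is NOT a shipped model.  The 43-node / 69-interaction Boolean
# model of stomatal closure regulation by abscisic acid (ABA) in
# Arabidopsis thaliana is published in its own source article and its rule
# table is not redistributed here.  To reproduce the wild-type and mutant
# analyses you must transcribe the published rules yourself into the
# native rule dialect of this package (see ?parse_network):
#
#     NodeName = expr          one rule per node; AND / OR / NOT, parens
#     NodeName = RANDOM        free node: fresh random state every update
#     clamp NodeName = True    hold a node fixed (stimulus or knockout)
#
# Node names may contain letters, digits, '_', '+' and '-', so species
# such as Ca2+_c are legal identifiers.
#
# Conventions used by the analyses this template feeds:
#   * The network input is ABA; simulations of hormone signaling clamp it
#     True ("clamp ABA = True" below).
#   * The output is "closure" (stomatal closure); use it with
#     efficiency_curve() / --efficiency.
#   * The knockout mutants are obtained by clamping S1P, PA, ABI1, pHc or
#     NOS False (apply_clamp() / --mutate), not by editing rules.
#   * GCR1 has no characterized regulation and is treated as a free node
#     ("GCR1 = RANDOM").  Whether further nodes are free is a modelling
#     decision left to the transcriber; mark each with "= RANDOM".
#
# Node names that appear in the analyses (fill in a rule for each, then
# add the remaining nodes of the published model):
#
#   ABA  closure  AnionEm  S1P  PA  ABI1  pHc  NOS  NO  GCR1  GPA1
#   KAP  KEV  KOUT  Ca2+_c  Ca2+ATPase  CIS  InsP3  PLC
#
# Example skeleton (uncomment and complete; parsing this file as-is fails
# with "empty network" on purpose, so a half-finished transcription is
# never mistaken for the real model):
#
# ABA = TRUE
# clamp ABA = True
# GCR1 = RANDOM
# S1P = ...
# closure = ...
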