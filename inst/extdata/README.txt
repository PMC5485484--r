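Category count tables (integer counts and printed percentages) reported
by a published drought-stress small RNA + degradome sequencing study of
Paulownia 'yuza 1' (control vs severely drought-stressed libraries).
Used as worked-example inputs for the table-arithmetic functions:
percentages are recomputed from the integer counts and compared with
the printed two-decimal values.

Headline tallies from the same study, used in cross-consistency checks:
raw reads 23,221,177; high-quality 23,168,277; clean 23,040,002 (99.45%
of high-quality); unannotated unique sRNAs 3,122,830 + 3,089,262 =
6,212,092; 32 conserved + 75 novel = 107 miRNAs; novel arms 34 (5p) +
41 (3p); 77 DE miRNAs (17 up + 60 down), 60 significant (16 up + 44
down); 42 target genes with 47 cleavage sites in t-plot categories
0..4 = 1, 1, 10, 1, 34.
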