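chr10	fgfr2trunc	transcript	1000001	1039466	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	exon	1000001	1000140	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "1";
chr10	fgfr2trunc	exon	1002141	1002280	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "2";
chr10	fgfr2trunc	exon	1004281	1004420	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "3";
chr10	fgfr2trunc	exon	1006421	1006560	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "4";
chr10	fgfr2trunc	exon	1008561	1008700	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "5";
chr10	fgfr2trunc	exon	1010701	1010840	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "6";
chr10	fgfr2trunc	exon	1012841	1012980	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "7";
chr10	fgfr2trunc	exon	1014981	1015120	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "8";
chr10	fgfr2trunc	exon	1017121	1017260	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "9";
chr10	fgfr2trunc	exon	1019261	1019400	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "10";
chr10	fgfr2trunc	exon	1021401	1021540	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "11";
chr10	fgfr2trunc	exon	1023541	1023680	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "12";
chr10	fgfr2trunc	exon	1025681	1025820	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "13";
chr10	fgfr2trunc	exon	1027821	1027960	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "14";
chr10	fgfr2trunc	exon	1029961	1030100	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "15";
chr10	fgfr2trunc	exon	1032101	1032240	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "16";
chr10	fgfr2trunc	exon	1034241	1034341	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "17";
chr10	fgfr2trunc	exon	1039342	1039466	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1"; exon_number "18";
chr10	fgfr2trunc	CDS	1000001	1000140	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1002141	1002280	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1004281	1004420	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1006421	1006560	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1008561	1008700	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1010701	1010840	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1012841	1012980	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1014981	1015120	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1017121	1017260	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1019261	1019400	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1021401	1021540	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1023541	1023680	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1025681	1025820	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1027821	1027960	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1029961	1030100	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1032101	1032240	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1034241	1034341	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	CDS	1039342	1039466	.	+	.	gene_id "FGFR2"; transcript_id "FGFR2.t1";
chr10	fgfr2trunc	transcript	2000001	2007293	.	+	.	gene_id "BICC1"; transcript_id "BICC1.t1";
chr10	fgfr2trunc	exon	2000001	2000100	.	+	.	gene_id "BICC1"; transcript_id "BICC1.t1"; exon_number "1";
chr10	fgfr2trunc	exon	2001601	2001800	.	+	.	gene_id "BICC1"; transcript_id "BICC1.t1"; exon_number "2";
chr10	fgfr2trunc	exon	2003301	2003600	.	+	.	gene_id "BICC1"; transcript_id "BICC1.t1"; exon_number "3";
chr10	fgfr2trunc	exon	2005101	2007293	.	+	.	gene_id "BICC1"; transcript_id "BICC1.t1"; exon_number "4";
chr10	fgfr2trunc	CDS	2000001	2000100	.	+	.	gene_id "BICC1"; transcript_id "BICC1.t1";
chr10	fgfr2trunc	CDS	2001601	2001800	.	+	.	gene_id "BICC1"; transcript_id "BICC1.t1";
chr10	fgfr2trunc	CDS	2003301	2003600	.	+	.	gene_id "BICC1"; transcript_id "BICC1.t1";
chr10	fgfr2trunc	CDS	2005101	2007293	.	+	.	gene_id "BICC1"; transcript_id "BICC1.t1";
chr11	fgfr2trunc	transcript	500001	502900	.	+	.	gene_id "TACC2"; transcript_id "TACC2.t1";
chr11	fgfr2trunc	exon	500001	500150	.	+	.	gene_id "TACC2"; transcript_id "TACC2.t1"; exon_number "1";
chr11	fgfr2trunc	exon	501151	501450	.	+	.	gene_id "TACC2"; transcript_id "TACC2.t1"; exon_number "2";
chr11	fgfr2trunc	exon	502451	502900	.	+	.	gene_id "TACC2"; transcript_id "TACC2.t1"; exon_number "3";
chr11	fgfr2trunc	CDS	500001	500150	.	+	.	gene_id "TACC2"; transcript_id "TACC2.t1";
chr11	fgfr2trunc	CDS	501151	501450	.	+	.	gene_id "TACC2"; transcript_id "TACC2.t1";
chr11	fgfr2trunc	CDS	502451	502900	.	+	.	gene_id "TACC2"; transcript_id "TACC2.t1";
chr11	fgfr2trunc	transcript	800001	803000	.	-	.	gene_id "ATE1"; transcript_id "ATE1.t1";
chr11	fgfr2trunc	exon	802781	803000	.	-	.	gene_id "ATE1"; transcript_id "ATE1.t1"; exon_number "1";
chr11	fgfr2trunc	exon	801381	801580	.	-	.	gene_id "ATE1"; transcript_id "ATE1.t1"; exon_number "2";
chr11	fgfr2trunc	exon	800001	800180	.	-	.	gene_id "ATE1"; transcript_id "ATE1.t1"; exon_number "3";
chr11	fgfr2trunc	CDS	802781	803000	.	-	.	gene_id "ATE1"; transcript_id "ATE1.t1";
chr11	fgfr2trunc	CDS	801381	801580	.	-	.	gene_id "ATE1"; transcript_id "ATE1.t1";
chr11	fgfr2trunc	CDS	800001	800180	.	-	.	gene_id "ATE1"; transcript_id "ATE1.t1";
chr10	fgfr2trunc	transcript	3000001	3003500	.	+	.	gene_id "LINC1"; transcript_id "LINC1.t1";
chr10	fgfr2trunc	exon	3000001	3000400	.	+	.	gene_id "LINC1"; transcript_id "LINC1.t1"; exon_number "1";
chr10	fgfr2trunc	exon	3002901	3003500	.	+	.	gene_id "LINC1"; transcript_id "LINC1.t1"; exon_number "2";
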