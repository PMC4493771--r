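pattern	n
+00	261
++0	169
-00	172
--0	55
-+0	776
-0+	434
+0+	293
-0-	164
0+0	148
00+	151
00-	107
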