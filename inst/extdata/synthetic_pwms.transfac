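AC  T00032
XX
NA  AP-1
XX
P0      A      C      G      T
01      1      1      1     15 T
02      1      1     15      1 G
03     15      1      1      1 A
04      1     15      1      1 C
05      1      1      1     15 T
06      1     15      1      1 C
07     15      1      1      1 A
XX
//
AC  T03461
XX
NA  CRX
XX
P0      A      C      G      T
01      1      1      1     15 T
02     15      1      1      1 A
03     15      1      1      1 A
04      1      1      1     15 T
05      1     15      1      1 C
06      1     15      1      1 C
XX
//
AC  T00588
XX
NA  NFkB
XX
P0      A      C      G      T
01      1      1     15      1 G
02      1      1     15      1 G
03      1      1     15      1 G
04     15      1      1      1 A
05      1     15      1      1 C
06      1      1      1     15 T
07      1      1      1     15 T
08      1      1      1     15 T
09      1     15      1      1 C
10      1     15      1      1 C
XX
//
AC  T03723
XX
NA  PNR
XX
P0      A      C      G      T
01     15      1      1      1 A
02     15      1      1      1 A
03      1      1     15      1 G
04      1      1      1     15 T
05      1     15      1      1 C
06     15      1      1      1 A
XX
//
AC  T01327
XX
NA  RARa
XX
P0      A      C      G      T
01     15      1      1      1 A
02      1      1     15      1 G
03      1      1     15      1 G
04      1      1      1     15 T
05      1     15      1      1 C
06     15      1      1      1 A
07     15      1      1      1 A
08      1      1     15      1 G
09      1      1     15      1 G
10      1      1      1     15 T
11      1     15      1      1 C
12     15      1      1      1 A
XX
//
AC  T01328
XX
NA  RARb
XX
P0      A      C      G      T
01     15      1      1      1 A
02      1      1     15      1 G
03      1      1     15      1 G
04      1      1      1     15 T
05      1     15      1      1 C
06     15      1      1      1 A
07      1     15      1      1 C
08     15      1      1      1 A
09      1      1     15      1 G
10      1      1     15      1 G
11      1      1      1     15 T
12      1     15      1      1 C
13     15      1      1      1 A
XX
//
AC  T01329
XX
NA  RARg
XX
P0      A      C      G      T
01     15      1      1      1 A
02      1      1     15      1 G
03      1      1     15      1 G
04      1      1      1     15 T
05      1     15      1      1 C
06     15      1      1      1 A
07     15      1      1      1 A
08     15      1      1      1 A
09      1      1     15      1 G
10      1      1     15      1 G
11      1      1      1     15 T
12      1     15      1      1 C
13     15      1      1      1 A
XX
//
AC  T01331
XX
NA  RXRa
XX
P0      A      C      G      T
01     15      1      1      1 A
02      1      1     15      1 G
03      1      1     15      1 G
04      1      1      1     15 T
05      1     15      1      1 C
06     15      1      1      1 A
07     15      1      1      1 A
08      1      1     15      1 G
09     15      1      1      1 A
10      1      1     15      1 G
11      1      1     15      1 G
12      1      1      1     15 T
13      1     15      1      1 C
14     15      1      1      1 A
XX
//
AC  T01332
XX
NA  RXRb
XX
P0      A      C      G      T
01      1      1     15      1 G
02      1      1     15      1 G
03      1      1     15      1 G
04      1      1      1     15 T
05      1     15      1      1 C
06     15      1      1      1 A
07     15      1      1      1 A
08     15      1      1      1 A
09      1      1     15      1 G
10      1      1     15      1 G
11      1      1      1     15 T
12      1     15      1      1 C
13     15      1      1      1 A
XX
//
AC  T01333
XX
NA  RXRg
XX
P0      A      C      G      T
01     15      1      1      1 A
02      1      1     15      1 G
03      1      1     15      1 G
04      1      1      1     15 T
05      1     15      1      1 C
06     15      1      1      1 A
07     15      1      1      1 A
08      1      1     15      1 G
09      1      1     15      1 G
10     15      1      1      1 A
11      1     15      1      1 C
12     15      1      1      1 A
XX
//
AC  T01173
XX
NA  THRa
XX
P0      A      C      G      T
01     15      1      1      1 A
02      1      1     15      1 G
03      1      1     15      1 G
04      1      1      1     15 T
05      1     15      1      1 C
06     15      1      1      1 A
07      1      1      1     15 T
08      1      1     15      1 G
09     15      1      1      1 A
10      1     15      1      1 C
11      1     15      1      1 C
12      1      1      1     15 T
XX
//
AC  T00851
XX
NA  THRb
XX
P0      A      C      G      T
01      1      1     15      1 G
02      1      1     15      1 G
03      1      1     15      1 G
04      1      1      1     15 T
05      1     15      1      1 C
06     15      1      1      1 A
07      1      1      1     15 T
08      1      1     15      1 G
09     15      1      1      1 A
10      1     15      1      1 C
11      1     15      1      1 C
12      1     15      1      1 C
XX
//
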