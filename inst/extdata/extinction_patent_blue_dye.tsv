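wavelength_nm	epsilon
450	1.3
451	1.5
452	1.7
453	1.9
454	2.1
455	2.4
456	2.7
457	3.1
458	3.5
459	4
460	4.5
461	5
462	5.7
463	6.4
464	7.2
465	8.1
466	9.1
467	10.3
468	11.5
469	12.9
470	14.5
471	16.2
472	18.2
473	20.4
474	22.8
475	25.4
476	28.4
477	31.7
478	35.4
479	39.4
480	43.9
481	48.9
482	54.3
483	60.4
484	67.1
485	74.4
486	82.5
487	91.5
488	101.3
489	112.1
490	124
491	137.1
492	151.4
493	167.1
494	184.3
495	203.2
496	223.8
497	246.3
498	270.9
499	297.8
500	327.1
501	359
502	393.7
503	431.6
504	472.7
505	517.4
506	566
507	618.7
508	675.8
509	737.7
510	804.6
511	877.1
512	955.4
513	1040
514	1131.3
515	1229.7
516	1335.8
517	1450.1
518	1573
519	1705.2
520	1847.2
521	1999.6
522	2163.1
523	2338.4
524	2526.1
525	2727
526	2941.8
527	3171.4
528	3416.5
529	3678
530	3956.8
531	4253.8
532	4569.9
533	4906
534	5263.3
535	5642.6
536	6045.2
537	6471.9
538	6924
539	7402.5
540	7908.6
541	8443.5
542	9008.3
543	9604.3
544	10232.6
545	10894.4
546	11591
547	12323.6
548	13093.4
549	13901.8
550	14749.7
551	15638.6
552	16569.6
553	17543.8
554	18562.5
555	19626.7
556	20737.5
557	21896.1
558	23103.4
559	24360.4
560	25667.9
561	27027
562	28438.3
563	29902.5
564	31420.4
565	32992.5
566	34619.3
567	36301.1
568	38038.3
569	39831
570	41679.4
571	43583.3
572	45542.7
573	47557.1
574	49626.4
575	51749.7
576	53926.6
577	56156.2
578	58437.4
579	60769.3
580	63150.4
581	65579.4
582	68054.7
583	70574.5
584	73136.9
585	75740
586	78381.3
587	81058.6
588	83769.4
589	86510.9
590	89280.2
591	92074.4
592	94890.3
593	97724.6
594	100573.9
595	103434.7
596	106303.1
597	109175.5
598	112047.9
599	114916.2
600	117776.4
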