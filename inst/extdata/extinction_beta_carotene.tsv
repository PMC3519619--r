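wavelength_nm	epsilon
450	130000
451	129710.9
452	129409.2
453	129081.6
454	128715.1
455	128297
456	127814.5
457	127255.3
458	126607.4
459	125859.4
460	125000
461	124020.7
462	122920.6
463	121700.7
464	120362.7
465	118908.7
466	117341.1
467	115662.9
468	113877.4
469	111988.4
470	110000
471	107915.7
472	105735.4
473	103459
474	101087.1
475	98621.2
476	96063.7
477	93418.2
478	90688.7
479	87880.7
480	85000
481	82055.1
482	79060.3
483	76031.1
484	72982.2
485	69927.6
486	66880.5
487	63853.3
488	60857.4
489	57903.1
490	55000
491	52156.3
492	49377.9
493	46670
494	44037.1
495	41483.2
496	39011.8
497	36625.7
498	34327.2
499	32118.2
500	30000
501	27973.8
502	26042
503	24206.1
504	22467
505	20824.4
506	19277.1
507	17823.6
508	16461.4
509	15188
510	14000
511	12894.1
512	11866.5
513	10913.5
514	10031
515	9215
516	8461.8
517	7767.4
518	7128.1
519	6540.1
520	6000
521	5504.2
522	5048.9
523	4630.4
524	4245.6
525	3891.6
526	3565.7
527	3265.6
528	2989.2
529	2734.6
530	2500
531	2283.9
532	2085.2
533	1902.9
534	1735.9
535	1583.2
536	1443.8
537	1316.7
538	1200.9
539	1095.6
540	1000
541	913.1
542	834.1
543	762
544	696.2
545	635.8
546	580.5
547	529.6
548	482.8
549	439.7
550	400
551	363.4
552	329.8
553	299
554	270.9
555	245.3
556	222.2
557	201.2
558	182.3
559	165.3
560	150
561	136.3
562	123.9
563	112.8
564	102.8
565	93.8
566	85.6
567	78.2
568	71.5
569	65.5
570	60
571	55
572	50.5
573	46.3
574	42.5
575	39
576	35.7
577	32.7
578	30
579	27.4
580	25
581	22.8
582	20.7
583	18.9
584	17.2
585	15.6
586	14.2
587	13
588	11.9
589	10.9
590	10
591	9.2
592	8.5
593	7.9
594	7.4
595	6.9
596	6.5
597	6.1
598	5.7
599	5.3
600	5
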